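# Co-prediction rule networks and per-rule visualization payloads.
# Nodes are feature=level conjuncts; an edge connects two conjuncts that
# co-occur in a retained rule, weighted by the rule's support and accuracy.

#' Build a co-prediction network for one decision class
#'
#' Retains the model's rules for `class_label` that pass the significance
#' and support filters, then connects every pair of conjuncts appearing
#' together in a retained rule.  Each rule contributes
#' `supp_rhs * accuracy` to the strength of its conjunct-pair edges
#' (an artifact choice: the simplest monotone combination of the two
#' quantities); a node's strength is the sum of its incident edge
#' strengths.
#'
#' @param model a `rule_model` with adjusted p-values.
#' @param class_label decision class of the subnetwork.
#' @param max_p_adjusted retain rules with adjusted p-value at or below
#'   this (default 0.05).
#' @param min_support retain rules with RHS support at least this
#'   (default 0).
#' @return a `rule_network`: `nodes` (feature, level, strength), `edges`
#'   (from, to, weight, contributing rule indices), `class_label`; both
#'   frames ordered by descending strength.  Empty (with a warning) when
#'   no rule passes the filter.
#' @export
build_network <- function(model, class_label, max_p_adjusted = 0.05,
                          min_support = 0) {
  r <- model$rules
  keep <- which(r$decision == class_label &
                  !is.na(r$p_adjusted) & r$p_adjusted <= max_p_adjusted &
                  r$supp_rhs >= min_support)
  if (length(keep) == 0L) {
    warning("no rules of class '", class_label, "' pass the filter")
    return(structure(list(
      nodes = data.frame(feature = character(0), level = character(0),
                         strength = numeric(0)),
      edges = data.frame(from = character(0), to = character(0),
                         weight = numeric(0), rules = character(0)),
      class_label = class_label), class = "rule_network"))
  }
  edge_w <- list()
  edge_rules <- list()
  node_names <- character(0)
  for (i in keep) {
    conj <- paste(r$features[[i]], r$levels[[i]], sep = "=")
    node_names <- union(node_names, conj)
    if (length(conj) < 2L) next
    w <- r$supp_rhs[i] * r$accuracy[i]
    pairs <- utils::combn(sort(conj), 2L)
    for (p in seq_len(ncol(pairs))) {
      key <- paste(pairs[1L, p], pairs[2L, p], sep = "~")
      edge_w[[key]] <- (edge_w[[key]] %||% 0) + w
      edge_rules[[key]] <- c(edge_rules[[key]], i)
    }
  }
  keys <- names(edge_w) %||% character(0)
  edges <- data.frame(
    from = vapply(strsplit(keys, "~", fixed = TRUE), `[`, character(1), 1L),
    to = vapply(strsplit(keys, "~", fixed = TRUE), `[`, character(1), 2L),
    weight = as.numeric(unlist(edge_w) %||% numeric(0)),
    rules = vapply(edge_rules, paste, character(1), collapse = ";") %||%
      character(0),
    stringsAsFactors = FALSE, row.names = NULL)
  strength <- vapply(node_names, function(nd)
    sum(edges$weight[edges$from == nd | edges$to == nd]), numeric(1))
  nodes <- data.frame(
    feature = vapply(strsplit(node_names, "=", fixed = TRUE), `[`,
                     character(1), 1L),
    level = vapply(strsplit(node_names, "=", fixed = TRUE), `[`,
                   character(1), 2L),
    strength = strength, stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[order(-nodes$strength, nodes$feature, nodes$level), ,
                 drop = FALSE]
  if (nrow(edges))
    edges <- edges[order(-edges$weight, edges$from, edges$to), ,
                   drop = FALSE]
  structure(list(nodes = nodes, edges = edges, class_label = class_label),
            class = "rule_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rule_network <- function(x, ...) {
  cat(sprintf("Co-prediction network for class '%s': %d nodes, %d edges\n",
              x$class_label, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a rule network as an edge list
#'
#' Writes a tab-separated edge list (`source`, `target`, `weight`,
#' `class`) loadable by standard graph tooling.
#'
#' @param net a `rule_network`.
#' @param path output file path.
#' @return the edge-list data.frame, invisibly.
#' @export
export_network <- function(net, path) {
  df <- data.frame(source = net$edges$from, target = net$edges$to,
                   weight = net$edges$weight, class = net$class_label,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}

#' Visualization payload for a single rule
#'
#' Splits the objects of a continuous companion table into three groups
#' relative to one rule: the rule's RHS support set, the remaining objects
#' of the rule's class, and the objects of the other class(es); and
#' collects each group's continuous values for every conjunct feature —
#' the data behind per-rule boxplots or heatmaps.
#'
#' @param model a `rule_model` whose statistics are current for the data
#'   the support sets refer to.
#' @param rule_index row index of the rule in `model$rules`.
#' @param dt the continuous (pre-discretization) [decision_table()],
#'   aligned with the model's training objects by object id.
#' @return a `rule_payload` list: `groups` (object-id vectors
#'   `supporting`, `same_class_nonsupport`, `other_class`) and `features`
#'   (per conjunct feature, the three groups' continuous values).
#' @export
rule_support_payload <- function(model, rule_index, dt) {
  r <- model$rules[rule_index, , drop = FALSE]
  supp <- r$support_set_rhs[[1L]]
  missing_ids <- setdiff(supp, dt$object_ids)
  if (length(missing_ids))
    stop("support-set object(s) absent from the companion table: ",
         paste(missing_ids, collapse = ", "))
  dsets <- decision_sets(dt)
  in_class <- dt$object_ids[vapply(dsets, function(s)
    r$decision %in% s, logical(1))]
  groups <- list(
    supporting = supp,
    same_class_nonsupport = setdiff(in_class, supp),
    other_class = setdiff(dt$object_ids, in_class))
  per_feature <- lapply(r$features[[1L]], function(f) {
    col <- dt$values[[f]]
    names(col) <- dt$object_ids
    lapply(groups, function(g) col[g])
  })
  names(per_feature) <- r$features[[1L]]
  structure(list(groups = groups, features = per_feature,
                 decision = r$decision),
            class = "rule_payload")
}
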