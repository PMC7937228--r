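# Indiscernibility partitions, rough approximations, the decision-relative
# discernibility family and exhaustive minimal-reduct enumeration.

#' Indiscernibility partition
#'
#' Two objects are indiscernible with respect to a feature subset B when
#' they agree on every feature of B; the relation is an equivalence and its
#' classes partition the universe.
#'
#' @param dt a discrete [decision_table()].
#' @param B character vector of feature names (may be empty: every object
#'   then falls into one block).
#' @return an `indiscernibility_partition`: list with `blocks` (list of
#'   object-id vectors, ordered by smallest contained object index) and
#'   `features` (B).
#' @export
indiscernibility_partition <- function(dt, B) {
  stopifnot_discrete(dt)
  unknown <- setdiff(B, feature_names(dt))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  idx <- block_indices(dt, B)
  structure(list(
    blocks   = lapply(idx, function(i) dt$object_ids[i]),
    features = B
  ), class = "indiscernibility_partition")
}

# Equivalence-class membership as row-index vectors, ordered by the
# smallest contained row index (deterministic).
block_indices <- function(dt, B) {
  n <- n_objects(dt)
  key <- if (length(B) == 0L) rep("", n)
         else do.call(paste, c(dt$values[B], sep = "\r"))
  groups <- split(seq_len(n), factor(key, levels = unique(key)))
  names(groups) <- NULL
  groups
}

#' @export
print.indiscernibility_partition <- function(x, ...) {
  cat(sprintf("Partition under {%s}: %d block(s)\n",
              paste(x$features, collapse = ", "), length(x$blocks)))
  for (b in x$blocks)
    cat("  {", paste(b, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Rough-set approximation regions
#'
#' Approximates a target object set X by the equivalence classes of the
#' B-indiscernibility relation.  The lower approximation collects blocks
#' fully inside X (objects certainly in X), the upper approximation blocks
#' intersecting X (objects possibly in X); their difference is the boundary
#' region, and objects certainly outside X form the outside region.
#'
#' @param dt a discrete [decision_table()].
#' @param B feature subset (character vector).
#' @param X target set of object ids.
#' @return an `approximation_regions` list with `lower`, `upper`,
#'   `boundary`, `outside`, `target` and `features`.
#' @export
approximate <- function(dt, B, X) {
  part <- indiscernibility_partition(dt, B)
  bad <- setdiff(X, dt$object_ids)
  if (length(bad)) stop("unknown object id(s): ", paste(bad, collapse = ", "))
  lower <- character(0)
  upper <- character(0)
  for (blk in part$blocks) {
    inter <- intersect(blk, X)
    if (length(inter)) upper <- c(upper, blk)
    if (length(inter) == length(blk)) lower <- c(lower, blk)
  }
  ord <- function(ids) ids[order(match(ids, dt$object_ids))]
  structure(list(
    lower    = ord(lower),
    upper    = ord(upper),
    boundary = ord(setdiff(upper, lower)),
    outside  = ord(setdiff(dt$object_ids, upper)),
    target   = X,
    features = B
  ), class = "approximation_regions")
}

#' @export
print.approximation_regions <- function(x, ...) {
  show <- function(lbl, ids)
    cat(sprintf("  %-8s {%s}\n", lbl, paste(ids, collapse = ", ")))
  cat(sprintf("Approximation of |X| = %d under {%s}:\n",
              length(x$target), paste(x$features, collapse = ", ")))
  show("lower", x$lower); show("upper", x$upper)
  show("boundary", x$boundary); show("outside", x$outside)
  invisible(x)
}

#' Generalized decision table
#'
#' Collapses a discrete table to one row per equivalence class of the full
#' feature set.  The decision of each row becomes the generalized decision:
#' the set of labels observed inside the class, encoded by joining the
#' sorted labels with `"|"` (boundary classes carry more than one label).
#' The cardinality of each class is kept as the `weights` attribute.
#'
#' @param dt a discrete [decision_table()].
#' @return a [decision_table()] with one row per equivalence class; row ids
#'   are the id of each class's first member.
#' @export
generalized_table <- function(dt) {
  stopifnot_discrete(dt)
  idx <- block_indices(dt, feature_names(dt))
  dsets <- decision_sets(dt)
  reps <- vapply(idx, `[`, integer(1), 1L)
  gdec <- vapply(idx, function(i)
    paste(sort(unique(unlist(dsets[i]))), collapse = "|"), character(1))
  out <- decision_table(dt$values[reps, , drop = FALSE], gdec,
                        decision_name = dt$decision_name,
                        object_ids = dt$object_ids[reps])
  attr(out, "weights") <- lengths(idx)
  attr(out, "members") <- lapply(idx, function(i) dt$object_ids[i])
  out
}

#' Decision-relative discernibility family
#'
#' Builds the clause family S of the discernibility function: for every
#' unordered pair of equivalence classes of the full feature set whose
#' generalized decisions differ (as sets), one clause holding the features
#' on which the two classes disagree.  A reduct is exactly a minimal
#' hitting set of this family.  Duplicate clauses are retained as a
#' multiset; they carry weight in the Johnson reducer.
#'
#' @param dt a discrete [decision_table()]; a single-class table yields an
#'   empty family (there is nothing to discern).
#' @return a `discernibility_family`: list with `clauses` (list of
#'   character vectors), `features` (the full feature set A) and
#'   `n_classes` (number of equivalence classes).
#' @export
discernibility_family <- function(dt) {
  stopifnot_discrete(dt)
  gt <- generalized_table(dt)
  a <- feature_names(gt)
  vm <- as.matrix(gt$values)        # character matrix, rows = classes
  gdec <- normalize_decision(gt$decisions)
  q <- nrow(vm)
  clauses <- vector("list", q * (q - 1L) / 2L)
  n <- 0L
  for (i in seq_len(q - 1L)) {
    for (j in (i + 1L):q) {
      if (gdec[i] == gdec[j]) next
      diffs <- a[vm[i, ] != vm[j, ]]
      # two decision-distinct classes always differ somewhere: identical
      # rows would have been merged into one class with a generalized
      # decision
      stopifnot(length(diffs) > 0L)
      n <- n + 1L
      clauses[[n]] <- diffs
    }
  }
  structure(list(clauses = clauses[seq_len(n)], features = a,
                 n_classes = q),
            class = "discernibility_family")
}

#' @export
print.discernibility_family <- function(x, ...) {
  cat(sprintf(
    "Discernibility family: %d clause(s) over %d feature(s), %d classes\n",
    length(x$clauses), length(x$features), x$n_classes))
  invisible(x)
}

#' @export
format.discernibility_family <- function(x, ...)
  vapply(x$clauses, paste, character(1), collapse = ",")

# Clause list as 0/1 membership matrix (clauses x features).
clause_matrix <- function(fam) {
  k <- length(fam$features)
  m <- matrix(0L, nrow = length(fam$clauses), ncol = k,
              dimnames = list(NULL, fam$features))
  for (i in seq_along(fam$clauses))
    m[i, match(fam$clauses[[i]], fam$features)] <- 1L
  m
}

# Superset absorption: drop clauses that contain another clause; preserves
# the Boolean function and shrinks the search.  Operates on a list of
# integer index vectors, returns a deduplicated list.
absorb_clauses <- function(cl) {
  cl <- unique(lapply(cl, sort))
  cl <- cl[order(lengths(cl))]
  keep <- rep(TRUE, length(cl))
  for (i in seq_along(cl)) {
    if (!keep[i]) next
    for (j in seq_along(cl)) {
      if (j == i || !keep[j]) next
      if (length(cl[[i]]) <= length(cl[[j]]) && all(cl[[i]] %in% cl[[j]]))
        keep[j] <- FALSE
    }
  }
  cl[keep]
}

# TRUE when the feature-index set `b` intersects every clause.
hits_all <- function(b, clauses)
  all(vapply(clauses, function(cl) any(cl %in% b), logical(1)))

#' Enumerate all minimal reducts (minimal hitting sets)
#'
#' Exhaustively enumerates the subset-minimal hitting sets of the
#' discernibility family, i.e. all prime implicants of the conjunctive
#' discernibility function; each one is a reduct.  The search is a
#' branch-and-bound over clauses after superset absorption; the problem is
#' NP-hard, so a hard cap on the feature count is enforced.
#'
#' @param fam a [discernibility_family()].
#' @param max_features refuse instances with more features than this
#'   (default 20); use the heuristic reducers beyond that.
#' @return list of reducts, each a list with `features` (character),
#'   `method = "exhaustive"` and `score` (reduct size); sorted by size,
#'   then lexicographically.
#' @seealso [johnson_reduct()], [genetic_reducts()]
#' @export
enumerate_minimal_hitting_sets <- function(fam, max_features = 20L) {
  a <- fam$features
  if (length(a) > max_features)
    stop("exhaustive enumeration capped at ", max_features,
         " features; use johnson_reduct() or genetic_reducts()")
  if (length(fam$clauses) == 0L) return(list())
  cl <- absorb_clauses(lapply(fam$clauses, function(s) match(s, a)))
  hits <- list()
  recurse <- function(remaining, partial) {
    if (length(remaining) == 0L) {
      hits[[length(hits) + 1L]] <<- sort(partial)
      return(invisible())
    }
    cand <- remaining[[which.min(lengths(remaining))]]
    for (f in cand) {
      keep <- remaining[!vapply(remaining, function(s) f %in% s, logical(1))]
      recurse(keep, c(partial, f))
    }
  }
  recurse(cl, integer(0))
  hits <- unique(hits)
  minimal <- vapply(hits, function(h) {
    !any(vapply(hits, function(o)
      length(o) < length(h) && all(o %in% h), logical(1)))
  }, logical(1))
  hits <- hits[minimal]
  feats <- lapply(hits, function(h) a[h])
  ord <- order(lengths(feats),
               vapply(feats, paste, character(1), collapse = "\r"))
  lapply(feats[ord], function(f)
    new_reduct(f, method = "exhaustive", score = length(f)))
}

new_reduct <- function(features, method, score = NA_real_) {
  structure(list(features = features, method = method, score = score),
            class = "reduct")
}

#' @export
print.reduct <- function(x, ...) {
  cat(sprintf("Reduct {%s} (%s, score %.4g)\n",
              paste(x$features, collapse = ", "), x$method, x$score))
  invisible(x)
}
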