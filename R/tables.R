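# Decision-table data model, delimited-text I/O and equal-frequency
# discretization.  A decision table is the universal learning input: a finite
# set of objects described by features (attributes) plus one designated
# decision (outcome) column.

#' Construct a decision table
#'
#' A decision table holds a finite universe of objects, a set of named
#' features (categorical or numeric) and one decision label per object.
#' It is the input structure for all learning operations in this package.
#'
#' @param values data.frame of feature columns (one row per object).
#'   Numeric columns are treated as continuous, everything else as discrete.
#' @param decisions vector of decision labels, one per object.
#' @param decision_name name of the decision column (must not clash with a
#'   feature name).
#' @param object_ids optional character vector of unique object identifiers;
#'   defaults to `o1..oN` or the row names of `values`.
#'
#' @return an object of class `decision_table` with fields `values`
#'   (data.frame of features), `decisions` (character), `object_ids`,
#'   `decision_name` and `value_kind` (per-feature `"continuous"` or
#'   `"discrete"`).
#'
#' @details Missing values are rejected: every downstream computation
#'   (indiscernibility, discernibility clauses, rule supports) assumes total
#'   information vectors.  Generalized decisions (several labels attached to
#'   one equivalence class) are encoded by joining the sorted labels with
#'   `"|"`, e.g. `"autism|control"`.
#'
#' @seealso [read_decision_table()], [fit_equal_frequency()]
#' @export
decision_table <- function(values, decisions, decision_name = "decision",
                           object_ids = NULL) {
  if (!is.data.frame(values)) values <- as.data.frame(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("decision table must have at least one object and one feature")
  if (length(decisions) != nrow(values))
    stop("need exactly one decision per object")
  if (anyNA(values) || anyNA(decisions))
    stop("missing values are not supported in decision tables")
  if (decision_name %in% names(values))
    stop("decision column name '", decision_name,
         "' duplicates a feature name")
  if (anyDuplicated(names(values)))
    stop("duplicate feature names")
  if (is.null(object_ids)) {
    object_ids <- if (!is.null(attr(values, "row.names")) &&
                      !is.integer(attr(values, "row.names")))
      rownames(values) else paste0("o", seq_len(nrow(values)))
  }
  object_ids <- as.character(object_ids)
  if (anyDuplicated(object_ids)) stop("duplicate object ids")
  if (length(object_ids) != nrow(values))
    stop("need exactly one id per object")
  rownames(values) <- NULL
  kind <- vapply(values, function(col) {
    if (is.numeric(col)) "continuous" else "discrete"
  }, character(1))
  values[] <- lapply(values, function(col) {
    if (is.numeric(col)) col else as.character(col)
  })
  structure(list(
    values        = values,
    decisions     = as.character(decisions),
    object_ids    = object_ids,
    decision_name = decision_name,
    value_kind    = kind
  ), class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("Decision table: %d objects x %d features, decision '%s'\n",
              n_objects(x), length(feature_names(x)), x$decision_name))
  n_cont <- sum(x$value_kind == "continuous")
  cat(sprintf("  features: %d continuous, %d discrete\n",
              n_cont, length(x$value_kind) - n_cont))
  tab <- table(x$decisions)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.decision_table <- function(x, row.names = NULL, optional = FALSE,
                                         ...) {
  out <- x$values
  out[[x$decision_name]] <- x$decisions
  rownames(out) <- x$object_ids
  out
}

#' @export
dim.decision_table <- function(x) c(length(x$object_ids),
                                    ncol(x$values) + 1L)

#' Number of objects in a decision table
#' @param dt a [decision_table()].
#' @return integer count of objects.
#' @export
n_objects <- function(dt) length(dt$object_ids)

#' Feature names of a decision table
#' @param dt a [decision_table()].
#' @return character vector of feature names (the set A).
#' @export
feature_names <- function(dt) names(dt$values)

#' Class labels of a decision table
#'
#' Returns the atomic decision labels in order of first appearance,
#' splitting generalized (pipe-joined) decisions into their components.
#'
#' @param dt a [decision_table()].
#' @return character vector of class labels.
#' @export
class_labels <- function(dt) unique(unlist(decision_sets(dt)))

# Per-object decision label sets: a generalized decision "a|b" becomes
# c("a", "b").  Plain labels come back as length-1 sets.
decision_sets <- function(dt) strsplit(dt$decisions, "|", fixed = TRUE)

# Normalize a decision label to a canonical generalized form (sorted,
# pipe-joined) so that "b|a" and "a|b" compare equal.
normalize_decision <- function(d) {
  vapply(strsplit(d, "|", fixed = TRUE),
         function(s) paste(sort(s), collapse = "|"), character(1))
}

# Subset a decision table by object index or id, keeping all features.
subset_objects <- function(dt, idx) {
  if (is.character(idx)) idx <- match(idx, dt$object_ids)
  decision_table(dt$values[idx, , drop = FALSE], dt$decisions[idx],
                 decision_name = dt$decision_name,
                 object_ids = dt$object_ids[idx])
}

stopifnot_discrete <- function(dt) {
  if (any(dt$value_kind == "continuous"))
    stop("operation requires a fully discrete table; ",
         "discretize continuous features first (see fit_equal_frequency)")
}

#' Read a decision table from delimited text
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param decision_column name of the decision column, or `"last"` (default)
#'   for the rightmost column.
#' @param delimiter field separator, default `","`.
#' @param id_column if `TRUE`, the first column holds object ids.
#'
#' @return a [decision_table()].  Numeric columns are typed continuous,
#'   everything else discrete; row and column order is preserved.
#' @export
read_decision_table <- function(path, decision_column = "last",
                                delimiter = ",", id_column = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (nrow(df) == 0L) stop("empty decision table: ", path)
  ids <- NULL
  if (id_column) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (identical(decision_column, "last"))
    decision_column <- names(df)[ncol(df)]
  if (!decision_column %in% names(df))
    stop("decision column '", decision_column, "' not found")
  decisions <- as.character(df[[decision_column]])
  values <- df[, setdiff(names(df), decision_column), drop = FALSE]
  if (ncol(values) == 0L) stop("table has no feature columns")
  decision_table(values, decisions, decision_name = decision_column,
                 object_ids = ids)
}

#' Write a decision table to delimited text
#'
#' @param dt a [decision_table()].
#' @param path output file path.
#' @param delimiter field separator, default `","`.
#' @param id_column if `TRUE`, write object ids as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(dt, path, delimiter = ",",
                                 id_column = FALSE) {
  out <- dt$values
  out[[dt$decision_name]] <- dt$decisions
  if (id_column) out <- cbind(id = dt$object_ids, out)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Fit an equal-frequency discretization map
#'
#' Computes per-feature cut points at the empirical quantiles of ranks
#' `k*m/bins` (`k = 1..bins-1`) so that the bins of the fitted data hold
#' equal numbers of objects up to ties.  Cuts are placed midway between the
#' order statistics bracketing each rank; tied order statistics cannot be
#' split, so ties merge bins rather than dividing a value across bins.
#'
#' @param dt a [decision_table()] with at least one continuous feature, or
#'   any table (discrete features pass through untouched).
#' @param bins number of bins, at least 2.  A feature with fewer distinct
#'   values than `bins` collapses to that many bins, with a warning.
#' @param labels optional bin label vector (e.g. `c("low","medium","high")`
#'   for three bins); default labels are `"1".."b"`.
#'
#' @return a `discretization_map`: per-feature strictly increasing cut
#'   points and bin labels.
#' @seealso [apply_discretization()]
#' @export
fit_equal_frequency <- function(dt, bins = 3L, labels = NULL) {
  if (bins < 2L) stop("bins must be at least 2")
  cont <- names(dt$value_kind)[dt$value_kind == "continuous"]
  cuts <- list()
  lab <- list()
  for (f in cont) {
    v <- sort(dt$values[[f]])
    m <- length(v)
    cand <- unique(vapply(seq_len(bins - 1L), function(k) {
      i <- ceiling(m * k / bins)
      if (i >= m) return(NA_real_)
      if (v[i] < v[i + 1L]) (v[i] + v[i + 1L]) / 2 else NA_real_
    }, numeric(1)))
    cand <- cand[!is.na(cand)]
    if (length(cand) < bins - 1L)
      warning("feature '", f, "' has fewer than ", bins,
              " resolvable bins; collapsed to ", length(cand) + 1L)
    cuts[[f]] <- cand
    b_eff <- length(cand) + 1L
    lab[[f]] <- if (is.null(labels)) as.character(seq_len(b_eff))
                else labels[seq_len(b_eff)]
  }
  structure(list(cuts = cuts, labels = lab, bins = as.integer(bins)),
            class = "discretization_map")
}

#' @export
print.discretization_map <- function(x, ...) {
  cat(sprintf("Equal-frequency discretization map: %d feature(s), %d bins\n",
              length(x$cuts), x$bins))
  for (f in names(x$cuts))
    cat("  ", f, ": cuts ", paste(signif(x$cuts[[f]], 6), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Apply a discretization map to a decision table
#'
#' Replaces every continuous feature by its bin label under the map's cut
#' points.  Values outside the fitted range clamp to the extreme bins, so a
#' map fitted on training data applies cleanly to test data.
#'
#' @param dt a [decision_table()].
#' @param map a map from [fit_equal_frequency()]; must cover every
#'   continuous feature of `dt`, and must not mention unknown features.
#' @return a fully discrete [decision_table()].
#' @export
apply_discretization <- function(dt, map) {
  unknown <- setdiff(names(map$cuts), feature_names(dt))
  if (length(unknown))
    stop("discretization map mentions unknown feature(s): ",
         paste(unknown, collapse = ", "))
  cont <- names(dt$value_kind)[dt$value_kind == "continuous"]
  uncovered <- setdiff(cont, names(map$cuts))
  if (length(uncovered))
    stop("map does not cover continuous feature(s): ",
         paste(uncovered, collapse = ", "))
  vals <- dt$values
  for (f in cont) {
    bin <- findInterval(vals[[f]], map$cuts[[f]]) + 1L
    vals[[f]] <- map$labels[[f]][bin]
  }
  decision_table(vals, dt$decisions, decision_name = dt$decision_name,
                 object_ids = dt$object_ids)
}
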