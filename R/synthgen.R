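# Synthetic decision-table generation: correlated Gaussian feature
# matrices via Cholesky factorization, exact class proportions and optional
# class-conditional mean shifts; plus the two worked-example fixture tables.

#' Exchangeable (compound-symmetry) covariance matrix
#'
#' @param k dimension.
#' @param rho common off-diagonal correlation; must keep the matrix
#'   positive definite (`rho > -1/(k-1)`).
#' @return a `k x k` covariance matrix with unit variances.
#' @export
exchangeable_covariance <- function(k, rho) {
  m <- matrix(rho, k, k)
  diag(m) <- 1
  m
}

#' Generate a synthetic decision table
#'
#' Draws a standard-normal object-by-feature matrix Z and multiplies it by
#' the transpose of the lower-triangular Cholesky factor L of the target
#' covariance D = L L^T, so each object's feature vector carries the
#' requested covariance.  Class labels are assigned deterministically by
#' largest-remainder rounding of the requested proportions (exact counts,
#' not Bernoulli draws, so imbalance ratios are reproduced exactly).  An
#' optional signal adds a mean shift of `effect_size` standard deviations
#' to the first `n_informative` features for one designated class.
#'
#' @param n_objects,n_features table dimensions.
#' @param class_labels class label vector (default `c("control","case")`).
#' @param proportions class proportions summing to 1.
#' @param covariance `NULL` / `"identity"` for independent features, or a
#'   positive-definite matrix (e.g. from [exchangeable_covariance()]).
#' @param n_informative number of features given a class-dependent shift.
#' @param effect_size mean shift in SD units (0 = null data: labels
#'   independent of features).
#' @param shift_class class receiving the shift; default the last label.
#' @param bins if `> 1`, discretize all features into this many
#'   equal-frequency bins before returning.
#' @param seed integer seed; output is fully reproducible.
#' @return a [decision_table()] with features `g1..gk`, objects `o1..on`
#'   and decision column `class`.
#' @export
synthesize_table <- function(n_objects, n_features,
                             class_labels = c("control", "case"),
                             proportions = c(0.5, 0.5),
                             covariance = NULL,
                             n_informative = 0L, effect_size = 0,
                             shift_class = NULL, bins = 0L, seed = 1L) {
  stopifnot(n_objects >= 1L, n_features >= 1L,
            length(class_labels) == length(proportions),
            n_informative <= n_features)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (is.null(shift_class)) shift_class <- class_labels[length(class_labels)]
  if (is.null(covariance) || identical(covariance, "identity"))
    covariance <- diag(n_features)
  if (!is.matrix(covariance) || nrow(covariance) != n_features ||
      ncol(covariance) != n_features)
    stop("covariance must be an n_features x n_features matrix")
  upper <- tryCatch(chol(covariance), error = function(e)
    stop("covariance specification is not positive definite: ",
         conditionMessage(e)))
  l_lower <- t(upper)                     # D = L %*% t(L)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  z <- matrix(stats::rnorm(n_objects * n_features), nrow = n_objects)
  x <- z %*% t(l_lower)
  colnames(x) <- paste0("g", seq_len(n_features))

  counts <- largest_remainder(proportions, n_objects)
  decisions <- rep(class_labels, counts)

  if (n_informative > 0L && effect_size != 0) {
    rows <- decisions == shift_class
    sds <- sqrt(diag(covariance))[seq_len(n_informative)]
    x[rows, seq_len(n_informative)] <-
      sweep(x[rows, seq_len(n_informative), drop = FALSE], 2L,
            effect_size * sds, `+`)
  }
  dt <- decision_table(as.data.frame(x), decisions, decision_name = "class",
                       object_ids = paste0("o", seq_len(n_objects)))
  if (bins > 1L)
    dt <- apply_discretization(dt, fit_equal_frequency(dt, bins))
  dt
}

# Exact class counts by largest-remainder rounding; ties break in label
# order so counts are deterministic.
largest_remainder <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Worked-example fixture tables
#'
#' Two small decision tables used throughout the documentation and tests:
#'
#' * `table1` — 5 objects, two discrete gene-expression features
#'   (`up`/`down`) and a `case`/`control` diagnosis.
#' * `table2` — a generalized table for a toy autism case-control study:
#'   8 equivalence classes over three genes (`low`/`medium`/`high`) plus a
#'   binary risk factor; the boundary classes `q4` and `q5` carry the
#'   generalized decision `"autism|control"`.
#'
#' @return named list of two [decision_table()]s, byte-stable across calls.
#' @export
fixture_tables <- function() {
  table1 <- decision_table(
    data.frame(
      gene1 = c("up", "up", "up", "down", "down"),
      gene2 = c("up", "down", "up", "down", "up"),
      stringsAsFactors = FALSE),
    decisions = c("case", "case", "control", "control", "case"),
    decision_name = "diagnosis",
    object_ids = paste0("x", 1:5))
  table2 <- decision_table(
    data.frame(
      g1 = c("low", "medium", "medium", "medium", "low", "low", "medium",
             "medium"),
      g2 = c("low", "medium", "low", "low", "low", "high", "high", "high"),
      g3 = c("medium", "medium", "medium", "high", "high", "medium",
             "medium", "high"),
      rf = c("yes", "yes", "yes", "no", "no", "no", "yes", "no"),
      stringsAsFactors = FALSE),
    decisions = c("autism", "autism", "autism", "autism|control",
                  "autism|control", "control", "control", "control"),
    decision_name = "diagnosis",
    object_ids = paste0("q", 1:8))
  list(table1 = table1, table2 = table2)
}
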