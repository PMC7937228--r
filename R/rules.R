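# Rule induction from reducts and the full statistical characterization of
# rules: supports, coverage, accuracy, hypergeometric significance with
# multiple-testing correction, risk ratios and support-set recapture.

#' Induce decision rules from reducts
#'
#' Each reduct is overlaid over all objects: every equivalence class of the
#' reduct's indiscernibility relation yields one rule per decision label
#' present in the class (boundary classes spawn one rule per label).  The
#' IF-part fixes the reduct features to the class's values; the THEN-part
#' is the decision label.  Duplicate rules arising from different reducts
#' are collapsed, and full statistics are computed on `dt`.
#'
#' @param dt a discrete [decision_table()].
#' @param reducts list of reducts (from any reducer) over `dt`'s features.
#' @param adjust multiple-testing correction applied to rule p-values
#'   (`"bonferroni"` default, see [adjust_pvalues()]).
#' @return a `rule_model`: ordered rule collection with statistics, class
#'   labels, per-class rule counts and training size.  Rules are sorted by
#'   decision, then descending RHS support, descending accuracy, and the
#'   conjunct string, so output is stable across runs.
#' @export
induce_rules <- function(dt, reducts, adjust = "bonferroni") {
  stopifnot_discrete(dt)
  classes <- class_labels(dt)
  if (length(reducts) == 0L) {
    warning("no reducts supplied; returning an empty model")
    return(new_rule_model(empty_rule_frame(), classes, NULL,
                          n_objects(dt), dt$decision_name, adjust))
  }
  dsets <- decision_sets(dt)
  feats <- list(); levs <- list(); decs <- character(0); srcs <- list()
  seen <- character(0)
  for (rd in reducts) {
    b <- rd$features
    bad <- setdiff(b, feature_names(dt))
    if (length(bad))
      stop("reduct mentions unknown feature(s): ", paste(bad, collapse = ", "))
    for (blk in block_indices(dt, b)) {
      vals <- as.character(unlist(dt$values[blk[1L], b, drop = FALSE]))
      for (d in sort(unique(unlist(dsets[blk])))) {
        key <- paste(paste(b, vals, sep = "="), collapse = "&")
        key <- paste(key, d, sep = "=>")
        if (key %in% seen) next
        seen <- c(seen, key)
        feats[[length(feats) + 1L]] <- b
        levs[[length(levs) + 1L]] <- vals
        decs <- c(decs, d)
        srcs[[length(srcs) + 1L]] <- b
      }
    }
  }
  rules <- data.frame(decision = decs, stringsAsFactors = FALSE)
  rules$features <- feats
  rules$levels <- levs
  rules$source_reduct <- srcs
  rules <- compute_rule_stats(rules, dt)
  rules <- order_rules(rules)
  model <- new_rule_model(rules, classes, NULL, n_objects(dt),
                          dt$decision_name, adjust)
  adjust_pvalues(model, adjust)
}

empty_rule_frame <- function() {
  df <- data.frame(decision = character(0), stringsAsFactors = FALSE)
  for (col in c("features", "levels", "source_reduct",
                "support_set_lhs", "support_set_rhs"))
    df[[col]] <- list()
  for (col in c("supp_lhs", "supp_rhs", "accuracy", "cov_rhs", "cov_lhs",
                "n_d", "n_o", "N", "p_value", "p_adjusted", "rr",
                "rr_ci_low", "rr_ci_high", "rr_p"))
    df[[col]] <- numeric(0)
  df$vacuous <- logical(0)
  df
}

new_rule_model <- function(rules, classes, discretization, training_size,
                           decision_name, adjust_method = "bonferroni") {
  rpc <- vapply(classes, function(cl) sum(rules$decision == cl), integer(1))
  structure(list(rules = rules, classes = classes,
                 rules_per_class = rpc,
                 discretization = discretization,
                 training_size = training_size,
                 decision_name = decision_name,
                 adjust_method = adjust_method,
                 accuracy_meta = NULL),
            class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf("Rule model: %d rule(s), %d class(es), trained on %d objects\n",
              nrow(x$rules), length(x$classes), x$training_size))
  cat("  rules per class:",
      paste(sprintf("%s (%d)", x$classes, x$rules_per_class),
            collapse = ", "), "\n")
  if (!is.null(x$accuracy_meta))
    cat(sprintf("  undersampling mean sub-model accuracy: %.3f\n",
                x$accuracy_meta))
  invisible(x)
}

# deterministic composite ordering: decision, -supp_rhs, -accuracy,
# lexical conjunct string
order_rules <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  conj <- mapply(function(f, l) paste(paste(f, l, sep = "="), collapse = "&"),
                 rules$features, rules$levels)
  rules[order(rules$decision, -rules$supp_rhs, -rules$accuracy, conj), ,
        drop = FALSE]
}

# Objects satisfying a rule's conjuncts, as a logical vector over dt rows.
lhs_match <- function(dt, features, levels) {
  sat <- rep(TRUE, n_objects(dt))
  for (i in seq_along(features)) {
    col <- dt$values[[features[i]]]
    if (is.null(col)) return(rep(FALSE, n_objects(dt)))
    sat <- sat & (col == levels[i])
  }
  sat
}

# Vectorized statistics for a rule frame against dt.  Counts:
#   y = objects satisfying the IF-part (LHS support),
#   x = those whose decision also matches (RHS support),
#   n_d = class size, n_o = N - n_d.
# coverage_RHS = x / n_d, coverage_LHS = y / n_d, accuracy = x / y.
compute_rule_stats <- function(rules, dt, conf_level = 0.95) {
  n <- n_objects(dt)
  dsets <- decision_sets(dt)
  class_members <- function(d)
    vapply(dsets, function(s) d %in% s, logical(1))
  nr <- nrow(rules)
  num <- function() numeric(nr)
  rules$supp_lhs <- num(); rules$supp_rhs <- num()
  rules$accuracy <- num(); rules$cov_rhs <- num(); rules$cov_lhs <- num()
  rules$n_d <- num(); rules$n_o <- num(); rules$N <- rep(n, nr)
  rules$p_value <- num(); rules$p_adjusted <- rep(NA_real_, nr)
  rules$rr <- num(); rules$rr_ci_low <- num(); rules$rr_ci_high <- num()
  rules$rr_p <- num()
  rules$vacuous <- logical(nr)
  rules$support_set_lhs <- vector("list", nr)
  rules$support_set_rhs <- vector("list", nr)
  for (i in seq_len(nr)) {
    sat <- lhs_match(dt, rules$features[[i]], rules$levels[[i]])
    ind <- class_members(rules$decision[i])
    y <- sum(sat)
    x <- sum(sat & ind)
    n_d <- sum(ind)
    rules$supp_lhs[i] <- y
    rules$supp_rhs[i] <- x
    rules$n_d[i] <- n_d
    rules$n_o[i] <- n - n_d
    rules$vacuous[i] <- y == 0L
    rules$accuracy[i] <- if (y > 0L) x / y else 0
    rules$cov_rhs[i] <- if (n_d > 0L) x / n_d else 0
    rules$cov_lhs[i] <- if (n_d > 0L) y / n_d else 0
    rules$support_set_lhs[[i]] <- dt$object_ids[sat]
    rules$support_set_rhs[[i]] <- dt$object_ids[sat & ind]
    rules$p_value[i] <- if (y > 0L)
      rule_pvalue(x, y, n_d, n - n_d, tail = "upper") else 1
    rr <- risk_ratio(x, y, n_d, n, conf_level = conf_level)
    rules$rr[i] <- rr$rr
    rules$rr_ci_low[i] <- rr$ci_low
    rules$rr_ci_high[i] <- rr$ci_high
    rules$rr_p[i] <- rr$p
  }
  rules
}

#' Hypergeometric rule p-value
#'
#' Models the RHS support of a rule as a draw of `y` objects (the LHS
#' support) from an urn of `N` objects containing `n_d` of the rule's class
#' and `n_o` of the other class(es):
#' `P(X = x) = choose(n_d, x) * choose(n_o, y - x) / choose(N, y)`.
#' The default upper tail `P(X >= x)` measures enrichment of the rule's
#' class within its support; `"point"` returns the probability mass itself.
#'
#' @param x RHS support (objects matching IF-part and class).
#' @param y LHS support (objects matching IF-part).
#' @param n_d objects of the rule's decision class.
#' @param n_o objects of the opposite class(es); `n_d + n_o` is the total
#'   object count N.
#' @param tail `"upper"` (default) or `"point"`.
#' @return a probability in `(0, 1]`.
#' @export
rule_pvalue <- function(x, y, n_d, n_o, tail = c("upper", "point")) {
  tail <- match.arg(tail)
  if (x < 0 || x > y || x > n_d || y - x > n_o)
    stop("combinatorially impossible rule support configuration")
  if (tail == "point") stats::dhyper(x, n_d, n_o, y)
  else stats::phyper(x - 1, n_d, n_o, y, lower.tail = FALSE)
}

#' Adjust rule p-values for multiple testing
#'
#' The family is the full set of rules in the model.  Bonferroni
#' (`p_adjusted = min(1, p * n_rules)`) is the default, protecting against
#' type-I errors across the potentially very large rule sets produced by
#' the genetic reducer; Holm and Benjamini-Hochberg are available for less
#' stringent control.
#'
#' @param model a `rule_model`.
#' @param method one of `"bonferroni"`, `"holm"`, `"bh"`, `"none"`.
#' @return the model with `p_adjusted` filled in.
#' @export
adjust_pvalues <- function(model, method = c("bonferroni", "holm", "bh",
                                             "none")) {
  method <- match.arg(method)
  r_method <- c(bonferroni = "bonferroni", holm = "holm", bh = "BH",
                none = "none")[[method]]
  model$rules$p_adjusted <- stats::p.adjust(model$rules$p_value,
                                            method = r_method)
  model$adjust_method <- method
  model
}

#' Risk ratio for a rule
#'
#' Treats the rule as an exposure: exposed objects satisfy the IF-part
#' (`y` of them, `x` with the outcome = rule's class), unexposed objects
#' do not (`N - y`, with `n_d - x` outcomes).  The risk ratio is
#' `rr = (x/y) / ((n_d - x)/(N - y))` with a log-normal confidence
#' interval `exp(log rr +/- z * se)`,
#' `se = sqrt(1/x - 1/y + 1/(n_d - x) - 1/(N - y))`, and a two-sided
#' normal-approximation p-value for `log rr = 0`.  Zero cells are handled
#' by a 0.5 continuity correction (flagged in the result).
#'
#' @param x,y,n_d,N rule support counts as in [rule_pvalue()]
#'   (`N = n_d + n_o`).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `rr`, `ci_low`, `ci_high`, `p` and `corrected`
#'   (continuity-correction flag).  When every object is exposed
#'   (`y == N`) the ratio is undefined and all values are `NA`.
#' @export
risk_ratio <- function(x, y, n_d, N, conf_level = 0.95) {
  if (y == 0)
    return(list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, corrected = FALSE))
  if (y == N)
    return(list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, corrected = FALSE))
  corrected <- FALSE
  xx <- x; yy <- y; cc <- n_d - x; uu <- N - y
  if (x == 0 || n_d - x == 0) {
    # zero cell in the 2x2 table: add 0.5 to each cell
    xx <- x + 0.5; cc <- n_d - x + 0.5; yy <- y + 1; uu <- N - y + 1
    corrected <- TRUE
  }
  rr <- (xx / yy) / (cc / uu)
  se <- sqrt(max(0, 1 / xx - 1 / yy + 1 / cc - 1 / uu))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0)  # degenerate table with no sampling variance
    return(list(rr = rr, ci_low = rr, ci_high = rr, p = 1,
                corrected = corrected))
  list(rr = rr,
       ci_low = exp(log(rr) - z * se),
       ci_high = exp(log(rr) + z * se),
       p = 2 * stats::pnorm(-abs(log(rr)) / se),
       corrected = corrected)
}

#' Recalculate rule statistics on a reference table
#'
#' Recomputes every rule's statistics (supports, coverage, accuracy,
#' p-values, risk ratios, support sets) against `dt`.  This is the
#' standard follow-up to undersampling ensembles: rules learned on balanced
#' subsets get their statistics restated on the full original training set.
#' Rules whose IF-part matches nothing in `dt` are retained but flagged
#' vacuous.
#'
#' @param model a `rule_model`.
#' @param dt a discrete [decision_table()] sharing the model's feature
#'   vocabulary.
#' @return the model with refreshed statistics (re-sorted and re-adjusted
#'   with the model's correction method).
#' @export
recalculate_rules <- function(model, dt) {
  stopifnot_discrete(dt)
  used <- unique(unlist(model$rules$features))
  missing_f <- setdiff(used, feature_names(dt))
  if (length(missing_f))
    stop("table lacks feature(s) used by the model: ",
         paste(missing_f, collapse = ", "))
  model$rules <- order_rules(compute_rule_stats(model$rules, dt))
  model$training_size <- n_objects(dt)
  model <- adjust_pvalues(model, model$adjust_method)
  model
}

#' Export a rule model as a delimited rule table
#'
#' Writes the interchange format consumed by rule-network visualization
#' tools: one row per rule with comma-joined features and levels, the
#' decision, the full statistics block and the semicolon-joined RHS
#' support set.
#'
#' @param model a `rule_model`.
#' @param path output file; `"\t"`-separated.
#' @return the exported data.frame, invisibly.
#' @export
export_rules <- function(model, path) {
  r <- model$rules
  df <- data.frame(
    FEATURES = vapply(r$features, paste, character(1), collapse = ","),
    LEVELS   = vapply(r$levels, paste, character(1), collapse = ","),
    DECISION = r$decision,
    SUPP_LHS = r$supp_lhs, SUPP_RHS = r$supp_rhs,
    ACC_RHS = r$accuracy, COV_RHS = r$cov_rhs, COV_LHS = r$cov_lhs,
    PVAL = r$p_value, PVAL_ADJ = r$p_adjusted,
    RR = r$rr, RR_CI_LOW = r$rr_ci_low, RR_CI_HIGH = r$rr_ci_high,
    RR_PVAL = r$rr_p,
    SUPPORT_SET_RHS = vapply(r$support_set_rhs, paste, character(1),
                             collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}
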