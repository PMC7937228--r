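# Voting-based prediction with vote normalization, stratified
# cross-validation, undersampling ensembles and permutation testing.

#' Predict classes by normalized rule voting
#'
#' Every object collects one vote from each unique rule whose IF-part it
#' satisfies, grouped by the rule's decision.  Because models often hold
#' unequal numbers of rules per class, the raw counts can be normalized by
#' a per-class scalar before the argmax: the mean, median or maximum of
#' that class's counts over the scored objects, the class's rule count
#' (`"rulnum"`), or the root of the sum of squared counts (`"rss"`).
#'
#' @param object a `rule_model`.
#' @param newdata a [decision_table()]; continuous tables are discretized
#'   automatically with the model's stored cuts.
#' @param normalization one of `"none"`, `"mean"`, `"median"`, `"max"`,
#'   `"rulnum"`, `"rss"`.
#' @param ... unused.
#' @return a `vote_tally` data.frame with one row per object: raw counts
#'   (`raw_<class>`), normalized scores (`score_<class>`), `predicted`
#'   (class label or `"unclassified"` when no rule fires), and a `tie`
#'   flag (ties break to the first class in training order).
#' @export
predict.rule_model <- function(object, newdata,
                               normalization = c("none", "mean", "median",
                                                 "max", "rulnum", "rss"),
                               ...) {
  normalization <- match.arg(normalization)
  dt <- newdata
  if (any(dt$value_kind == "continuous")) {
    if (is.null(object$discretization))
      stop("continuous input but the model stores no discretization map")
    dt <- apply_discretization(dt, object$discretization)
  }
  n <- n_objects(dt)
  classes <- object$classes
  r <- object$rules
  raw <- matrix(0, nrow = n, ncol = length(classes),
                dimnames = list(NULL, classes))
  if (nrow(r) > 0L) {
    fired <- vapply(seq_len(nrow(r)), function(i)
      lhs_match(dt, r$features[[i]], r$levels[[i]]), logical(n))
    fired <- matrix(fired, nrow = n)   # n x n_rules
    for (cl in classes) {
      sel <- which(r$decision == cl)
      if (length(sel))
        raw[, cl] <- rowSums(fired[, sel, drop = FALSE])
    }
  }
  scalars <- vapply(classes, function(cl) {
    s <- switch(normalization,
                none   = 1,
                mean   = mean(raw[, cl]),
                median = stats::median(raw[, cl]),
                max    = max(raw[, cl]),
                rulnum = object$rules_per_class[[cl]],
                rss    = sqrt(sum(raw[, cl]^2)))
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
  scores <- sweep(raw, 2L, scalars, `/`)
  any_vote <- rowSums(raw) > 0
  best <- apply(scores, 1L, which.max)    # first class wins ties
  tie <- apply(scores, 1L, function(s) sum(s == max(s)) > 1L) & any_vote
  predicted <- ifelse(any_vote, classes[best], "unclassified")
  out <- data.frame(object_id = dt$object_ids, stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("raw_", cl)]] <- raw[, cl]
  for (cl in classes) out[[paste0("score_", cl)]] <- scores[, cl]
  out$predicted <- predicted
  out$tie <- tie
  attr(out, "normalization") <- normalization
  attr(out, "classes") <- classes
  class(out) <- c("vote_tally", "data.frame")
  out
}

#' Pipeline configuration for model training
#'
#' @param reducer `"johnson"` (one greedy reduct), `"genetic"` (GA search)
#'   or `"exhaustive"` (all minimal reducts; capped feature count).
#' @param bins equal-frequency bins for continuous features (default 3).
#' @param normalization vote normalization for prediction (default
#'   `"none"`, plain majority voting).
#' @param undersample train as a class-balanced undersampling ensemble.
#' @param accuracy_folds internal CV folds for the balanced sub-model
#'   accuracy estimate when undersampling (see [undersample_train()]).
#' @param adjust p-value correction method for rule statistics.
#' @param positive_class class treated as positive for ROC/AUC; default
#'   the lexicographically last label.
#' @param genetic a [genetic_params()] object for `reducer = "genetic"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reducer = c("johnson", "genetic", "exhaustive"),
                            bins = 3L, normalization = "none",
                            undersample = FALSE, accuracy_folds = 5L,
                            adjust = "bonferroni", positive_class = NULL,
                            genetic = genetic_params()) {
  structure(list(reducer = match.arg(reducer), bins = as.integer(bins),
                 normalization = normalization, undersample = undersample,
                 accuracy_folds = as.integer(accuracy_folds),
                 adjust = adjust, positive_class = positive_class,
                 genetic = genetic),
            class = "pipeline_config")
}

#' Train a rule model on a discrete decision table
#'
#' Builds the discernibility family, computes reducts with the configured
#' reducer and induces the rule model.  `seed` feeds the genetic reducer
#' only: Johnson and exhaustive enumeration are deterministic.
#'
#' @param dt a discrete [decision_table()] with at least 2 classes.
#' @param config a [pipeline_config()].
#' @param seed integer seed for stochastic reducers.
#' @return a `rule_model`.
#' @export
train_rule_model <- function(dt, config = pipeline_config(), seed = 1L) {
  stopifnot_discrete(dt)
  if (length(class_labels(dt)) < 2L)
    stop("training requires at least 2 decision classes")
  fam <- discernibility_family(dt)
  if (length(fam$clauses) == 0L)
    return(new_rule_model(empty_rule_frame(), class_labels(dt), NULL,
                          n_objects(dt), dt$decision_name, config$adjust))
  reducts <- switch(config$reducer,
    johnson    = list(johnson_reduct(fam)),
    genetic    = {
      gp <- config$genetic
      gp$seed <- as.integer(seed)
      genetic_reducts(fam, gp)
    },
    exhaustive = enumerate_minimal_hitting_sets(fam))
  induce_rules(dt, reducts, adjust = config$adjust)
}

# Rank-based (Mann-Whitney) AUC with midrank tie handling.
auc_from_scores <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Per-object ranking score for the positive class: difference between the
# normalized positive-class score and the best other class's score.
positive_scores <- function(tally, positive) {
  classes <- attr(tally, "classes")
  others <- setdiff(classes, positive)
  s_pos <- tally[[paste0("score_", positive)]]
  if (length(others) == 0L) return(s_pos)
  s_neg <- do.call(pmax, lapply(others, function(cl)
    tally[[paste0("score_", cl)]]))
  s_pos - s_neg
}

#' Stratified cross-validation of the rule-learning pipeline
#'
#' Splits the objects into class-stratified folds; for each fold the
#' discretization cuts are fitted on the training part only, a rule model
#' is trained (optionally as an undersampling ensemble) and the held-out
#' objects are predicted by normalized voting.  Unclassified objects count
#' as errors.  The AUC is computed from the pooled normalized scores of
#' the positive class.
#'
#' @param dt a [decision_table()] (continuous or discrete).
#' @param config a [pipeline_config()].
#' @param folds number of folds (default 10); reduced with a warning if a
#'   class has fewer members.
#' @param seed integer seed driving fold assignment (and any stochastic
#'   training step).
#' @return a `cv_result`: per-fold accuracies and confusion counts,
#'   `mean_accuracy` (held-out, mean over folds), `pooled_accuracy` (over
#'   pooled predictions), `model_accuracy` (mean of each fold model's own
#'   accuracy estimate: for undersampling ensembles the average balanced
#'   sub-model accuracy, otherwise `NA`), `auc`, `positive_class`, `seed`,
#'   `fold_count`.
#' @export
cross_validate <- function(dt, config = pipeline_config(), folds = 10L,
                           seed = 1L) {
  classes <- class_labels(dt)
  if (length(classes) < 2L) stop("need at least 2 classes")
  positive <- if (is.null(config$positive_class)) max(classes)
              else config$positive_class
  min_class <- min(table(dt$decisions))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " objects; reducing folds")
    folds <- max(2L, as.integer(min_class))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(n_objects(dt))
  for (cl in unique(dt$decisions)) {
    idx <- sample(which(dt$decisions == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  # objects with generalized labels (if any) get folds too
  rest <- which(fold_of == 0L)
  if (length(rest)) fold_of[rest] <- rep_len(seq_len(folds), length(rest))

  per_fold <- data.frame(fold = seq_len(folds), accuracy = NA_real_,
                         model_accuracy = NA_real_)
  pooled_pred <- character(n_objects(dt))
  pooled_score <- numeric(n_objects(dt))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train <- subset_objects(dt, which(fold_of != f))
    test <- subset_objects(dt, test_idx)
    if (any(train$value_kind == "continuous")) {
      map <- fit_equal_frequency(train, config$bins)
      train_d <- apply_discretization(train, map)
      test_d <- apply_discretization(test, map)
    } else {
      map <- NULL; train_d <- train; test_d <- test
    }
    # derived per-fold seed, kept inside 32-bit integer range
    fold_seed <- as.integer((as.numeric(seed) * 1009 + f) %% 2147483647)
    model <- if (isTRUE(config$undersample))
      undersample_train(train_d, config = config, seed = fold_seed,
                        accuracy_folds = config$accuracy_folds %||% 5L)
    else train_rule_model(train_d, config, seed = fold_seed)
    model$discretization <- map
    tally <- predict(model, test_d, normalization = config$normalization)
    per_fold$accuracy[f] <- mean(tally$predicted == test$decisions)
    per_fold$model_accuracy[f] <- model$accuracy_meta %||% NA_real_
    pooled_pred[test_idx] <- tally$predicted
    pooled_score[test_idx] <- positive_scores(tally, positive)
  }
  structure(list(
    folds = per_fold,
    mean_accuracy = mean(per_fold$accuracy),
    model_accuracy = if (all(is.na(per_fold$model_accuracy))) NA_real_
                     else mean(per_fold$model_accuracy),
    pooled_accuracy = mean(pooled_pred == dt$decisions),
    auc = auc_from_scores(pooled_score, dt$decisions, positive),
    confusion = table(predicted = pooled_pred, truth = dt$decisions),
    positive_class = positive,
    seed = seed, fold_count = folds,
    fold_assignment = fold_of
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: mean accuracy %.3f, pooled accuracy %.3f, AUC %.3f\n",
    x$fold_count, x$mean_accuracy, x$pooled_accuracy, x$auc))
  invisible(x)
}

#' Undersampling configuration
#'
#' @param n_sets number of balanced subsets, or `"auto"` (default):
#'   `ceiling(n_majority / n_minority)`, enough for every majority object
#'   to be drawn at least once.
#' @param set_size majority draw per subset, or `"auto"` (= minority
#'   class size).
#' @param require_full_coverage arrange the majority draws so their union
#'   covers the whole majority class (default `TRUE`).
#' @return an `undersample_config` list.
#' @export
undersample_config <- function(n_sets = "auto", set_size = "auto",
                               require_full_coverage = TRUE) {
  structure(list(n_sets = n_sets, set_size = set_size,
                 require_full_coverage = require_full_coverage),
            class = "undersample_config")
}

#' Train a class-balanced model by undersampling the majority class
#'
#' Builds balanced subsets, each holding every minority-class object plus
#' a without-replacement draw of equal size from each larger class; the
#' draws are arranged as consecutive slices of one random permutation per
#' class, so their union covers that class.  A rule model is trained on
#' each subset and the models are merged keeping unique rules; the
#' merged model's `accuracy_meta` is the mean resubstitution accuracy of
#' the sub-models.  Statistics of the merged rules should then be restated
#' on the full table with [recalculate_rules()] (done automatically inside
#' [cross_validate()]).
#'
#' @param dt a discrete [decision_table()] with at least 2 classes.
#' @param cfg an [undersample_config()].
#' @param config a [pipeline_config()] controlling the sub-model training.
#' @param seed integer seed for the draws.
#' @param accuracy_folds folds of the small internal cross-validation that
#'   estimates each sub-model's accuracy on its balanced subset (default
#'   2, kept low for speed); `0` falls back to resubstitution accuracy.
#'   Because the subsets are balanced, this estimate is free of the
#'   majority-class bias that inflates accuracy on imbalanced data.
#' @return a merged `rule_model`.
#' @export
undersample_train <- function(dt, cfg = undersample_config(),
                              config = pipeline_config(), seed = 1L,
                              accuracy_folds = 5L) {
  stopifnot_discrete(dt)
  counts <- table(dt$decisions)
  if (length(counts) < 2L) stop("need at least 2 classes")
  m <- if (identical(cfg$set_size, "auto")) min(counts)
       else as.integer(cfg$set_size)
  if (m > min(counts))
    stop("set_size exceeds the minority class size (", min(counts), ")")
  n_sets <- if (identical(cfg$n_sets, "auto"))
    as.integer(ceiling(max(counts) / m)) else as.integer(cfg$n_sets)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  perms <- lapply(names(counts), function(cl) sample(which(dt$decisions == cl)))
  names(perms) <- names(counts)
  slice <- function(perm, s) {
    n_c <- length(perm)
    if (n_c == m) return(perm)
    if (isTRUE(cfg$require_full_coverage)) {
      # consecutive cyclic slices of one permutation: the union over
      # ceiling(n_c / m) slices is the whole class, each slice distinct
      pos <- ((s - 1L) * m + seq_len(m) - 1L) %% n_c + 1L
      perm[pos]
    } else sample(perm, m)
  }
  sub_config <- config
  sub_config$undersample <- FALSE
  sub_models <- vector("list", n_sets)
  sub_acc <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    idx <- sort(unlist(lapply(perms, slice, s = s)))
    sub <- subset_objects(dt, idx)
    sub_seed <- as.integer((as.numeric(seed) + s) %% 2147483647)
    mod <- train_rule_model(sub, sub_config, seed = sub_seed)
    sub_acc[s] <- if (accuracy_folds >= 2L) {
      suppressWarnings(
        cross_validate(sub, sub_config, folds = accuracy_folds,
                       seed = sub_seed)$mean_accuracy)
    } else {
      tally <- predict(mod, sub, normalization = config$normalization)
      mean(tally$predicted == sub$decisions)
    }
    sub_models[[s]] <- mod
  }
  merged <- merge_rule_models(sub_models, classes = class_labels(dt),
                              decision_name = dt$decision_name,
                              adjust = config$adjust)
  merged$accuracy_meta <- mean(sub_acc)
  merged$training_size <- n_objects(dt)
  recalculate_rules(merged, dt)
}

# Merge rule models keeping unique (conditions, decision) rules; statistics
# are those of the first model contributing each rule until recalculated.
merge_rule_models <- function(models, classes, decision_name,
                              adjust = "bonferroni") {
  all_rules <- do.call(rbind, lapply(models, function(m) m$rules))
  if (is.null(all_rules) || nrow(all_rules) == 0L)
    return(new_rule_model(empty_rule_frame(), classes, NULL, 0L,
                          decision_name, adjust))
  key <- vapply(seq_len(nrow(all_rules)), function(i)
    paste(paste(all_rules$features[[i]], all_rules$levels[[i]], sep = "="),
          collapse = "&"), character(1))
  key <- paste(key, all_rules$decision, sep = "=>")
  uniq <- !duplicated(key)
  new_rule_model(order_rules(all_rules[uniq, , drop = FALSE]), classes,
                 NULL, max(vapply(models, function(m) m$training_size,
                                  numeric(1))),
                 decision_name, adjust)
}

#' Label-permutation significance test for a trained pipeline
#'
#' Shuffles the decision labels `n_perm` times, reruns the full
#' cross-validated pipeline on each shuffled table, and compares the null
#' accuracies and AUCs with the observed ones.  Empirical p-values use the
#' add-one estimator `p = (1 + #(null >= observed)) / (1 + n_perm)`, so a
#' model beating all 100 shuffles reports `p = 1/101 <= 0.01`.
#'
#' @param dt a [decision_table()].
#' @param config a [pipeline_config()].
#' @param folds CV folds per model fit.
#' @param n_perm number of label shuffles (default 100).
#' @param seed integer seed.
#' @return a `permutation_test` list: `p_accuracy`, `p_auc`, `observed`
#'   (the cv_result), `null_accuracy` and `null_auc` distributions.
#' @export
permutation_test <- function(dt, config = pipeline_config(), folds = 10L,
                             n_perm = 100L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draw_seeds <- sample.int(2147483646L, n_perm + 1L)
  observed <- cross_validate(dt, config, folds, seed = draw_seeds[1L])
  null_acc <- numeric(n_perm)
  null_auc <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(draw_seeds[i + 1L])
    shuffled <- dt
    shuffled$decisions <- sample(dt$decisions)
    res <- cross_validate(shuffled, config, folds, seed = draw_seeds[i + 1L])
    null_acc[i] <- res$mean_accuracy
    null_auc[i] <- res$auc
  }
  structure(list(
    p_accuracy = (1 + sum(null_acc >= observed$mean_accuracy)) / (1 + n_perm),
    p_auc = (1 + sum(null_auc >= observed$auc)) / (1 + n_perm),
    observed = observed,
    null_accuracy = null_acc,
    null_auc = null_auc,
    n_perm = n_perm, seed = seed
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%d shuffles): p[accuracy] = %.4f, p[AUC] = %.4f\n",
    x$n_perm, x$p_accuracy, x$p_auc))
  invisible(x)
}
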