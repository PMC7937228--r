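# Build a small hand-specified model: 4 control rules, 1 case rule.
make_vote_model <- function() {
  rules <- data.frame(
    decision = c("control", "control", "control", "control", "case"),
    stringsAsFactors = FALSE)
  rules$features <- list("g1", "g2", c("g1", "g2"), "g3", "g1")
  rules$levels <- list("a", "a", c("a", "a"), "a", "a")
  rules$source_reduct <- rules$features
  rules$supp_lhs <- 1
  rules$supp_rhs <- 1
  rules$accuracy <- 1
  roughrules:::new_rule_model(rules, classes = c("control", "case"),
                              discretization = NULL, training_size = 10,
                              decision_name = "d")
}

test_that("raw majority voting and the unclassified sentinel behave", {
  m <- make_vote_model()
  dt <- decision_table(
    data.frame(g1 = c("a", "b"), g2 = c("a", "b"), g3 = c("b", "b"),
               stringsAsFactors = FALSE), c("control", "case"))
  tal <- predict(m, dt, normalization = "none")
  # object 1 fires 3 control rules and 1 case rule
  expect_equal(tal$raw_control[1], 3)
  expect_equal(tal$raw_case[1], 1)
  expect_equal(tal$predicted[1], "control")
  expect_false(tal$tie[1])
  # object 2 fires nothing
  expect_equal(tal$predicted[2], "unclassified")
})

test_that("rule-count normalization corrects rule imbalance", {
  m <- make_vote_model()
  dt <- decision_table(
    data.frame(g1 = "a", g2 = "b", g3 = "b", stringsAsFactors = FALSE),
    "case")
  # raw votes (control 1, case 1): a tie under plain voting, broken to the
  # first training class...
  plain <- predict(m, dt, normalization = "none")
  expect_true(plain$tie[1])
  expect_equal(plain$predicted[1], "control")
  # ...but rulnum divides by (4 control, 1 case) rules: 0.25 vs 1
  rn <- predict(m, dt, normalization = "rulnum")
  expect_equal(rn$score_control[1], 0.25)
  expect_equal(rn$score_case[1], 1)
  expect_equal(rn$predicted[1], "case")
})

test_that("normalization preserves within-class score ordering", {
  dt <- synthesize_table(60, 3, bins = 3, seed = 21)
  model <- train_rule_model(dt, pipeline_config(reducer = "exhaustive"))
  base <- predict(model, dt, normalization = "none")
  for (norm in c("mean", "median", "max", "rulnum", "rss")) {
    tal <- predict(model, dt, normalization = norm)
    for (cl in model$classes) {
      col <- paste0("score_", cl)
      expect_equal(order(tal[[col]]), order(base[[col]]), info = norm)
    }
  }
})

test_that("the worked-example model classifies the first equivalence class", {
  t2 <- fixture_tables()$table2
  m <- induce_rules(t2, list(manual_reduct(c("g2", "rf"))))
  tal <- predict(m, t2)
  expect_equal(tal$predicted[tal$object_id == "q1"], "autism")
})

test_that("cross-validation is perfect on a separable table", {
  set.seed(1)
  n <- 60
  dec <- rep(c("case", "control"), each = n / 2)
  dt <- decision_table(
    data.frame(signal = ifelse(dec == "case", "hi", "lo"),
               noise = sample(c("p", "q"), n, TRUE),
               stringsAsFactors = FALSE), dec)
  cv <- cross_validate(dt, pipeline_config(), folds = 5, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$auc, 1)
})

test_that("fold assignment is a stratified partition", {
  dt <- synthesize_table(55, 2, proportions = c(0.6, 0.4), seed = 8)
  cv <- cross_validate(dt, pipeline_config(), folds = 5, seed = 2)
  f <- cv$fold_assignment
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 55L)
  for (cl in class_labels(dt)) {
    per_fold <- table(f[dt$decisions == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_warning(cross_validate(dt, pipeline_config(), folds = 50,
                                seed = 2), "reducing folds")
})

test_that("balanced input degenerates to a single full-table subset", {
  dt <- synthesize_table(40, 2, bins = 3, seed = 31)
  um <- undersample_train(dt, config = pipeline_config(), seed = 1,
                          accuracy_folds = 0)
  plain <- train_rule_model(dt, pipeline_config())
  key <- function(m) mapply(function(f, l, d)
    paste0(paste(f, l, sep = "=", collapse = "&"), "=>", d),
    m$rules$features, m$rules$levels, m$rules$decision)
  expect_setequal(key(um), key(plain))
})

test_that("undersampling subsets are balanced and cover the majority class", {
  dt <- synthesize_table(15, 2, proportions = c(2 / 3, 1 / 3), bins = 3,
                         seed = 5)
  counts <- table(dt$decisions)
  expect_equal(as.vector(counts), c(5L, 10L))  # case minority, control maj
  # reach into the sampling logic through a tiny n_sets trace: train with
  # auto settings and verify every rule-support object can appear, then
  # check the draw arithmetic directly
  set.seed(1)
  perm <- sample(which(dt$decisions == "control"))
  s1 <- perm[((0 * 5 + 1:5 - 1) %% 10) + 1]
  s2 <- perm[((1 * 5 + 1:5 - 1) %% 10) + 1]
  expect_equal(sort(c(s1, s2)), sort(perm))     # union covers the class
  expect_equal(anyDuplicated(s1), 0L)           # within-draw no replacement
  um <- undersample_train(dt, config = pipeline_config(), seed = 1,
                          accuracy_folds = 0)
  # merged model holds no duplicate (conditions, decision) pairs
  key <- mapply(function(f, l, d)
    paste0(paste(f, l, sep = "=", collapse = "&"), "=>", d),
    um$rules$features, um$rules$levels, um$rules$decision)
  expect_equal(anyDuplicated(key), 0L)
  expect_error(undersample_train(dt, undersample_config(set_size = 6),
                                 config = pipeline_config()),
               "minority")
})

test_that("permutation p-values follow the add-one estimator", {
  set.seed(2)
  n <- 24
  dec <- rep(c("case", "control"), each = n / 2)
  dt <- decision_table(
    data.frame(signal = ifelse(dec == "case", "hi", "lo"),
               noise = sample(c("p", "q"), n, TRUE),
               stringsAsFactors = FALSE), dec)
  pt <- permutation_test(dt, pipeline_config(), folds = 3, n_perm = 4,
                         seed = 5)
  # the observed model is perfect; no shuffled model can beat or tie it
  expect_equal(pt$observed$mean_accuracy, 1)
  expect_equal(pt$p_accuracy, 1 / 5)
  expect_equal(pt$p_auc, 1 / 5)
  expect_length(pt$null_accuracy, 4L)
  expect_true(all(pt$null_accuracy < 1))
})
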