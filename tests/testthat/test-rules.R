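fx <- fixture_tables()
t1 <- fx$table1
t2 <- fx$table2

rule_key <- function(model) {
  mapply(function(f, l, d)
    paste0(paste(f, l, sep = "=", collapse = "&"), "=>", d),
    model$rules$features, model$rules$levels, model$rules$decision)
}

test_that("overlaying a reduct induces the worked-example rule", {
  m <- induce_rules(t2, list(manual_reduct(c("g2", "rf"))))
  expect_true("g2=low&rf=yes=>autism" %in% rule_key(m))
})

test_that("rule statistics count supports on the training table", {
  m <- induce_rules(t1, list(manual_reduct(c("gene1", "gene2"))))
  r <- m$rules
  k <- rule_key(m)
  # singleton block {x2}: exact rule
  i <- which(k == "gene1=up&gene2=down=>case")
  expect_equal(r$supp_lhs[i], 1)
  expect_equal(r$supp_rhs[i], 1)
  expect_equal(r$accuracy[i], 1)
  # boundary block {x1, x3} spawns one rule per label, accuracy 1/2
  for (d in c("case", "control")) {
    j <- which(k == paste0("gene1=up&gene2=up=>", d))
    expect_equal(r$supp_lhs[j], 2)
    expect_equal(r$supp_rhs[j], 1)
    expect_equal(r$accuracy[j], 0.5)
  }
  # coverage uses the class size: n_case = 3
  i_case <- which(k == "gene1=up&gene2=up=>case")
  expect_equal(r$cov_rhs[i_case], 1 / 3)
  expect_equal(r$cov_lhs[i_case], 2 / 3)
  expect_equal(r$support_set_lhs[[i_case]], c("x1", "x3"))
  expect_equal(r$support_set_rhs[[i_case]], "x1")
  # integer identity accuracy * supp_lhs == supp_rhs
  expect_equal(r$accuracy * r$supp_lhs, r$supp_rhs)
})

test_that("duplicate rules from overlapping reducts collapse to one", {
  m <- induce_rules(t2, list(manual_reduct(c("g2", "rf")),
                             manual_reduct(c("g2", "rf")),
                             manual_reduct(c("g2", "g3"))))
  expect_equal(anyDuplicated(rule_key(m)), 0L)
  expect_warning(m0 <- induce_rules(t1, list()), "no reducts")
  expect_equal(nrow(m0$rules), 0L)
})

test_that("hypergeometric p-values: hand example, edge case, oracle", {
  # N=5, n_d=3, n_o=2, y=2, x=2: C(3,2) C(2,0) / C(5,2) = 3/10
  expect_equal(rule_pvalue(2, 2, 3, 2, tail = "point"), 0.3)
  expect_equal(rule_pvalue(2, 2, 3, 2, tail = "upper"), 0.3)
  # n_o = 0 and x = y: the only possible outcome
  expect_equal(rule_pvalue(4, 4, 4, 0, tail = "point"), 1)
  expect_equal(rule_pvalue(4, 4, 4, 0, tail = "upper"), 1)
  expect_error(rule_pvalue(3, 2, 3, 2), "impossible")
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    n_d <- sample(seq_len(n - 1L), 1)
    y <- sample(seq_len(n), 1)
    lo <- max(0L, y - (n - n_d))
    x <- sample(lo:min(y, n_d), 1)
    expect_equal(rule_pvalue(x, y, n_d, n - n_d, tail = "upper"),
                 hyper_tail_oracle(x, y, n_d, n), tolerance = 1e-12)
  }
})

test_that("multiple-testing adjustment follows the standard recurrences", {
  m <- induce_rules(t1, list(manual_reduct(c("gene1", "gene2"))))
  m$rules$p_value <- c(0.004, 0.5, 0.01, 0.02, 0.03)[seq_len(nrow(m$rules))]
  bf <- adjust_pvalues(m, "bonferroni")
  expect_equal(bf$rules$p_adjusted, pmin(1, m$rules$p_value * nrow(m$rules)))
  expect_true(all(diff(bf$rules$p_adjusted[order(m$rules$p_value)]) >= 0))
  m4 <- m
  m4$rules <- m$rules[1:4, ]
  m4$rules$p_value <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(m4, "bh")$rules$p_adjusted, rep(0.04, 4))
  expect_equal(adjust_pvalues(m4, "none")$rules$p_adjusted,
               m4$rules$p_value)
})

test_that("risk ratios match direct 2x2 arithmetic", {
  rr <- risk_ratio(13, 16, 30, 60)
  expect_false(rr$corrected)
  expect_equal(rr$rr, (13 / 16) / ((30 - 13) / (60 - 16)))
  se <- sqrt(1 / 13 - 1 / 16 + 1 / 17 - 1 / 44)
  expect_equal(rr$ci_low, exp(log(rr$rr) - qnorm(0.975) * se))
  expect_equal(rr$ci_high, exp(log(rr$rr) + qnorm(0.975) * se))
  expect_equal(rr$p, 2 * pnorm(-abs(log(rr$rr)) / se))
  # no-association identity
  expect_equal(risk_ratio(1, 2, 2, 4)$rr, 1)
  # all of the class inside the LHS: zero unexposed-outcome cell,
  # continuity correction keeps the CI finite
  b <- risk_ratio(5, 8, 5, 20)
  expect_true(b$corrected)
  expect_true(is.finite(b$ci_high) && b$ci_high > b$rr)
  # everybody exposed: undefined
  expect_true(is.na(risk_ratio(3, 6, 3, 6)$rr))
})

test_that("recalculation is idempotent on the training table", {
  m <- induce_rules(t2, list(manual_reduct(c("g2", "rf"))))
  m2 <- recalculate_rules(m, t2)
  expect_equal(m2$rules$supp_lhs, m$rules$supp_lhs)
  expect_equal(m2$rules$p_value, m$rules$p_value)
  expect_equal(m2$rules$rr, m$rules$rr)
  expect_equal(rule_key(m2), rule_key(m))
})

test_that("recalculating a subset-trained model never shrinks supports", {
  dt <- synthesize_table(40, 3, bins = 3, seed = 9)
  sub <- roughrules:::subset_objects(dt, 1:20)
  m <- induce_rules(sub, list(manual_reduct(feature_names(dt))))
  full <- recalculate_rules(m, dt)
  key_sub <- rule_key(m)
  key_full <- rule_key(full)
  idx <- match(key_sub, key_full)
  expect_true(all(full$rules$supp_lhs[idx] >= m$rules$supp_lhs))
  expect_true(all(full$rules$supp_rhs[idx] >= m$rules$supp_rhs))
})

test_that("rules with vocabulary absent from the table are flagged vacuous", {
  m <- induce_rules(t1, list(manual_reduct("gene1")))
  alien <- decision_table(
    data.frame(gene1 = c("sideways", "sideways"),
               stringsAsFactors = FALSE),
    c("case", "control"))
  m2 <- recalculate_rules(m, alien)
  expect_true(all(m2$rules$vacuous))
  expect_true(all(m2$rules$accuracy == 0))
  expect_error(recalculate_rules(m, decision_table(
    data.frame(other = c("1", "2")), c("a", "b"))), "lacks feature")
})

test_that("the rule-table export carries the interchange columns", {
  m <- induce_rules(t2, list(manual_reduct(c("g2", "rf"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- export_rules(m, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(back),
               c("FEATURES", "LEVELS", "DECISION", "SUPP_LHS", "SUPP_RHS",
                 "ACC_RHS", "COV_RHS", "COV_LHS", "PVAL", "PVAL_ADJ", "RR",
                 "RR_CI_LOW", "RR_CI_HIGH", "RR_PVAL", "SUPPORT_SET_RHS"))
  expect_equal(nrow(back), nrow(m$rules))
  expect_true(all(grepl(",", back$FEATURES)))
})
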