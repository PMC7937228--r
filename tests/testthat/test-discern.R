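fx <- fixture_tables()
t1 <- fx$table1
t2 <- fx$table2

test_that("the three worked-example partitions are reproduced", {
  expect_equal(indiscernibility_partition(t1, "gene1")$blocks,
               list(c("x1", "x2", "x3"), c("x4", "x5")))
  expect_equal(indiscernibility_partition(t1, "gene2")$blocks,
               list(c("x1", "x3", "x5"), c("x2", "x4")))
  expect_equal(indiscernibility_partition(t1, c("gene1", "gene2"))$blocks,
               list(c("x1", "x3"), "x2", "x4", "x5"))
  expect_equal(indiscernibility_partition(t1, character(0))$blocks,
               list(paste0("x", 1:5)))
  expect_error(indiscernibility_partition(t1, "geneX"), "unknown feature")
})

test_that("approximation regions match the worked example and edge cases", {
  cases <- t1$object_ids[t1$decisions == "case"]
  r <- approximate(t1, feature_names(t1), cases)
  expect_equal(r$lower, c("x2", "x5"))
  expect_equal(r$upper, c("x1", "x2", "x3", "x5"))
  expect_equal(r$boundary, c("x1", "x3"))
  expect_equal(r$outside, "x4")

  all_u <- approximate(t1, feature_names(t1), t1$object_ids)
  expect_equal(all_u$lower, t1$object_ids)
  expect_equal(all_u$boundary, character(0))
  none <- approximate(t1, feature_names(t1), character(0))
  expect_equal(none$upper, character(0))
  expect_equal(none$outside, t1$object_ids)
})

test_that("rough-set sandwich and refinement hold on random tables", {
  for (seed in 1:15) {
    dt <- random_discrete_table(sample(4:15, 1), sample(2:5, 1),
                                n_levels = 2, seed = seed)
    a <- feature_names(dt)
    b2 <- sample(a, sample(seq_along(a), 1))
    b1 <- sample(b2, sample(seq_along(b2), 1))
    x <- sample(dt$object_ids, sample(0:n_objects(dt), 1))
    r <- approximate(dt, b2, x)
    expect_true(all(r$lower %in% x))
    expect_true(all(x %in% r$upper))
    # refinement: each block of IND(B2) sits inside a block of IND(B1)
    p1 <- indiscernibility_partition(dt, b1)$blocks
    p2 <- indiscernibility_partition(dt, b2)$blocks
    for (blk in p2)
      expect_equal(sum(vapply(p1, function(coarse)
        all(blk %in% coarse), logical(1))), 1L)
  }
})

test_that("generalized tables merge indiscernible objects and pool labels", {
  gt <- generalized_table(t1)
  expect_equal(n_objects(gt), 4L)
  i <- which(gt$object_ids == "x1")
  expect_equal(gt$decisions[i], "case|control")
  expect_equal(attr(gt, "members")[[i]], c("x1", "x3"))
  expect_equal(attr(gt, "weights")[i], 2L)

  dup <- decision_table(data.frame(a = c("1", "1"), b = c("2", "2")),
                        c("case", "control"))
  gdup <- generalized_table(dup)
  expect_equal(n_objects(gdup), 1L)
  expect_equal(gdup$decisions, "case|control")

  distinct <- decision_table(data.frame(a = c("1", "2")), c("x", "y"))
  expect_equal(as.data.frame(generalized_table(distinct)),
               as.data.frame(distinct))
})

test_that("the worked-example discernibility family has the printed clauses", {
  fam <- discernibility_family(t2)
  expect_length(fam$clauses, 21L)
  keys <- sort(vapply(fam$clauses, function(cl)
    paste(sort(cl), collapse = ","), character(1)))
  counts <- table(keys)
  # multiset counts transcribed from the printed conjunctive form
  expect_equal(counts[["g2"]], 3L)
  expect_equal(counts[["g1,g2"]], 2L)
  expect_equal(counts[["g3,rf"]], 2L)
  expect_equal(counts[["g2,g3,rf"]], 4L)
  expect_equal(counts[["g1,g2,g3,rf"]], 3L)
  expect_equal(counts[["g2,g3"]], 1L)
  expect_equal(counts[["g2,rf"]], 1L)
  # q1 vs q4 differ on g1, g3 and rf
  expect_true("g1,g3,rf" %in% keys)
})

test_that("family edge cases: single clause, single class", {
  two <- decision_table(data.frame(a = c("1", "2")), c("x", "y"))
  fam <- discernibility_family(two)
  expect_equal(fam$clauses, list("a"))
  one_class <- decision_table(data.frame(a = c("1", "2")), c("x", "x"))
  expect_length(discernibility_family(one_class)$clauses, 0L)
})

test_that("exhaustive enumeration finds exactly the two worked reducts", {
  reds <- enumerate_minimal_hitting_sets(discernibility_family(t2))
  expect_equal(reduct_feature_sets(reds),
               list(c("g2", "g3"), c("g2", "rf")))
  single <- structure(list(clauses = list("a"), features = "a",
                           n_classes = 2L),
                      class = "discernibility_family")
  expect_equal(reduct_feature_sets(enumerate_minimal_hitting_sets(single)),
               list("a"))
  big <- structure(list(clauses = list("a"),
                        features = paste0("f", 1:25), n_classes = 2L),
                   class = "discernibility_family")
  expect_error(enumerate_minimal_hitting_sets(big), "capped")
})

test_that("enumeration agrees with the 2^|A| brute-force oracle", {
  for (seed in 1:25) {
    dt <- random_discrete_table(sample(4:20, 1), sample(2:8, 1),
                                n_levels = sample(2:3, 1), seed = 100 + seed)
    fam <- discernibility_family(dt)
    if (length(fam$clauses) == 0L) next
    expect_equal(reduct_feature_sets(enumerate_minimal_hitting_sets(fam)),
                 brute_force_mhs(fam), info = paste("seed", seed))
  }
})

test_that("every enumerated reduct preserves decision discernibility", {
  for (seed in 1:10) {
    dt <- random_discrete_table(sample(5:12, 1), sample(2:5, 1),
                                seed = 200 + seed)
    fam <- discernibility_family(dt)
    if (length(fam$clauses) == 0L) next
    gt <- generalized_table(dt)
    gdec <- roughrules:::normalize_decision(gt$decisions)
    discerned_pairs <- function(b) {
      vm <- as.matrix(gt$values[, b, drop = FALSE])
      out <- character(0)
      for (i in seq_len(nrow(vm) - 1L)) for (j in (i + 1L):nrow(vm))
        if (gdec[i] != gdec[j] && any(vm[i, ] != vm[j, ]))
          out <- c(out, paste(i, j))
      out
    }
    full <- discerned_pairs(feature_names(dt))
    for (rd in enumerate_minimal_hitting_sets(fam))
      expect_equal(discerned_pairs(rd$features), full)
  }
})
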