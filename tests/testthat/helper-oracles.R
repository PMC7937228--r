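# Shared fixtures and independent oracles for the property tests.

# Random fully-discrete decision table; always contains >= 2 classes.
random_discrete_table <- function(n_objects, n_features, n_levels = 2L,
                                  n_classes = 2L, seed = 1L) {
  set.seed(seed)
  vals <- as.data.frame(matrix(
    sample(letters[seq_len(n_levels)], n_objects * n_features,
           replace = TRUE),
    nrow = n_objects), stringsAsFactors = FALSE)
  names(vals) <- paste0("f", seq_len(n_features))
  decisions <- sample(paste0("c", seq_len(n_classes)), n_objects,
                      replace = TRUE)
  decisions[seq_len(min(n_objects, n_classes))] <-
    paste0("c", seq_len(min(n_objects, n_classes)))
  decision_table(vals, decisions)
}

# Brute-force minimal-hitting-set oracle: scan all 2^|A| feature subsets,
# keep hitting sets, filter to subset-minimal.  Independent of the
# branch-and-bound path.
brute_force_mhs <- function(fam) {
  a <- fam$features
  k <- length(a)
  if (length(fam$clauses) == 0L) return(list())
  hitting <- list()
  for (mask in seq_len(2^k - 1L)) {
    b <- a[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L]
    ok <- all(vapply(fam$clauses, function(cl) any(cl %in% b), logical(1)))
    if (ok) hitting[[length(hitting) + 1L]] <- sort(b)
  }
  minimal <- vapply(hitting, function(h) {
    !any(vapply(hitting, function(o)
      length(o) < length(h) && all(o %in% h), logical(1)))
  }, logical(1))
  out <- hitting[minimal]
  out[order(lengths(out),
            vapply(out, paste, character(1), collapse = "\r"))]
}

is_hitting_set <- function(features, fam)
  all(vapply(fam$clauses, function(cl) any(cl %in% features), logical(1)))

# Exhaustive draw-enumeration oracle for the hypergeometric upper tail:
# enumerate every size-y draw from N objects of which the first n_d carry
# the decision class, and count draws with at least x class members.
hyper_tail_oracle <- function(x, y, n_d, N) {
  draws <- utils::combn(N, y)
  hits <- colSums(draws <= n_d)
  mean(hits >= x)
}

reduct_feature_sets <- function(reducts)
  lapply(reducts, function(r) sort(r$features))

# Hand-rolled reduct constructor for tests that bypass the reducers.
manual_reduct <- function(features)
  structure(list(features = features, method = "exhaustive",
                 score = length(features)), class = "reduct")
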