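# Heuristic reduct search: the Johnson greedy weighted set-cover heuristic
# and a genetic-algorithm hitting-set search.

#' Johnson greedy reduct
#'
#' Greedy weighted set cover over the discernibility clause family:
#' starting from an empty set, repeatedly add the feature maximizing the
#' total weight of the still-uncovered clauses containing it, remove the
#' clauses it covers, and stop when every clause is covered.  Ties break on
#' the lowest feature index in A, so the result is deterministic.  Because
#' greedy choices can leave redundant features behind, the result is
#' post-processed to subset-minimality by reverse-order redundancy
#' elimination (on by default).
#'
#' @param fam a [discernibility_family()] (nonempty).
#' @param weights positive clause weights, one per clause; default 1 per
#'   clause occurrence, so duplicated clauses count double.
#' @param minimize drop redundant features from the greedy result
#'   (default `TRUE`).
#' @return a single reduct (`method = "johnson"`, score = total clause
#'   weight covered).
#' @export
johnson_reduct <- function(fam, weights = NULL, minimize = TRUE) {
  n_cl <- length(fam$clauses)
  if (n_cl == 0L) stop("empty discernibility family: nothing to cover")
  if (is.null(weights)) weights <- rep(1, n_cl)
  if (length(weights) != n_cl || any(weights <= 0))
    stop("weights must be strictly positive, one per clause")
  a <- fam$features
  m <- clause_matrix(fam)
  uncovered <- rep(TRUE, n_cl)
  r <- integer(0)
  while (any(uncovered)) {
    w <- colSums(m[uncovered, , drop = FALSE] * weights[uncovered])
    pick <- which.max(w)          # first index wins on ties
    r <- c(r, pick)
    uncovered <- uncovered & m[, pick] == 0L
  }
  if (minimize && length(r) > 1L) {
    for (f in rev(r)) {
      cand <- setdiff(r, f)
      if (all(rowSums(m[, cand, drop = FALSE]) > 0L)) r <- cand
    }
  }
  new_reduct(a[sort(r)], method = "johnson", score = sum(weights))
}

#' Genetic-reducer parameters
#'
#' @param alpha trade-off in `[0,1]` between subset cost and hitting
#'   fraction in the fitness function (default 0.9 leans on hitting).
#' @param epsilon approximation degree in `(0,1]`: subsets hitting at least
#'   this fraction of clauses enter the keep-list (default 1, exact
#'   hitting sets only).
#' @param cost function mapping a feature-name vector to a nonnegative
#'   cost; default cardinality.
#' @param population_size,generations,crossover_prob,mutation_prob,elite_count
#'   genetic-algorithm controls; `mutation_prob = NULL` means `1/|A|`
#'   per bit.
#' @param keep_list_size maximum number of distinct kept subsets.
#' @param seed integer seed; the search is reproducible given the seed.
#' @return a `genetic_params` list.
#' @export
genetic_params <- function(alpha = 0.9, epsilon = 1.0, cost = NULL,
                           population_size = 70L, generations = 200L,
                           crossover_prob = 0.6, mutation_prob = NULL,
                           elite_count = 2L, keep_list_size = 256L,
                           seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0, epsilon <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            population_size >= 2L)
  structure(list(alpha = alpha, epsilon = epsilon, cost = cost,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elite_count = as.integer(elite_count),
                 keep_list_size = as.integer(keep_list_size),
                 seed = as.integer(seed)),
            class = "genetic_params")
}

# Fitness of bitstring subsets B (rows of `pop`):
#   f(B) = (1-alpha) * (cost(A) - cost(B)) / cost(A)
#        + alpha * min(epsilon, |{S in family : S intersects B}| / |family|)
# rewarding cheap subsets that hit (almost) every clause.
genetic_fitness <- function(hitfrac, costs, cost_a, alpha, epsilon) {
  (1 - alpha) * (cost_a - costs) / cost_a + alpha * pmin(epsilon, hitfrac)
}

#' Genetic-algorithm reduct search
#'
#' Evolves a population of bitstring-encoded feature subsets under a
#' fitness that rewards hitting sets: a convex combination (weight
#' `alpha`) of the normalized cost saving over the full feature set and
#' the fraction of discernibility clauses hit, capped at the approximation
#' degree `epsilon`.  Every subset whose hitting fraction reaches
#' `epsilon` is recorded in a keep-list; the keep-list is reduced to
#' subset-minimal hitting sets before returning.  Selection is binary
#' tournament with elitism, one-point crossover and per-bit mutation.
#'
#' @param fam a [discernibility_family()] (nonempty).
#' @param params a [genetic_params()] object.
#' @return list of distinct reducts (`method = "genetic"`, score =
#'   fitness), sorted by size then lexicographically.  With
#'   `epsilon = 1` every returned set is a true hitting set; if none is
#'   found within the budget a warning is raised and the best-effort list
#'   returned.
#' @export
genetic_reducts <- function(fam, params = genetic_params()) {
  n_cl <- length(fam$clauses)
  if (n_cl == 0L) stop("empty discernibility family: nothing to cover")
  a <- fam$features
  k <- length(a)
  m <- clause_matrix(fam)
  cost_fn <- if (is.null(params$cost)) length else params$cost
  cost_a <- cost_fn(a)
  p_mut <- if (is.null(params$mutation_prob)) 1 / k else params$mutation_prob
  pop_n <- params$population_size

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  pop <- matrix(rbinom(pop_n * k, 1L, 0.5), nrow = pop_n, ncol = k)
  kept <- new.env(parent = emptyenv())

  record_hits <- function(pop, hitfrac) {
    ok <- which(hitfrac >= params$epsilon & rowSums(pop) > 0L)
    for (i in ok) {
      key <- paste(pop[i, ], collapse = "")
      if (is.null(kept[[key]])) kept[[key]] <- which(pop[i, ] == 1L)
    }
  }

  for (gen in seq_len(params$generations)) {
    costs <- vapply(seq_len(pop_n), function(i)
      cost_fn(a[pop[i, ] == 1L]), numeric(1))
    hitfrac <- colMeans(m %*% t(pop) > 0L)
    fit <- genetic_fitness(hitfrac, costs, cost_a, params$alpha,
                           params$epsilon)
    record_hits(pop, hitfrac)
    if (length(ls(kept)) >= params$keep_list_size) break

    elite <- order(fit, decreasing = TRUE)[seq_len(params$elite_count)]
    nxt <- matrix(0L, nrow = pop_n, ncol = k)
    nxt[seq_along(elite), ] <- pop[elite, , drop = FALSE]
    i <- length(elite)
    while (i < pop_n) {
      # binary tournament selection
      pick <- function() {
        c2 <- sample.int(pop_n, 2L)
        c2[which.max(fit[c2])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      if (runif(1) < params$crossover_prob && k > 1L) {
        cut <- sample.int(k - 1L, 1L)
        child1 <- c(p1[seq_len(cut)], p2[(cut + 1L):k])
        child2 <- c(p2[seq_len(cut)], p1[(cut + 1L):k])
      } else {
        child1 <- p1; child2 <- p2
      }
      for (ch in list(child1, child2)) {
        if (i >= pop_n) break
        flip <- runif(k) < p_mut
        ch[flip] <- 1L - ch[flip]
        i <- i + 1L
        nxt[i, ] <- ch
      }
    }
    pop <- nxt
  }

  keys <- ls(kept)
  if (length(keys) == 0L) {
    warning("genetic search found no subset with hitting fraction >= ",
            params$epsilon, " within budget; returning empty list")
    return(list())
  }
  subsets <- lapply(keys, function(kk) kept[[kk]])
  # reduce each kept subset to a subset-minimal hitting set
  minimized <- lapply(subsets, function(b) {
    for (f in rev(b)) {
      cand <- setdiff(b, f)
      if (length(cand) > 0L &&
          all(rowSums(m[, cand, drop = FALSE]) > 0L)) b <- cand
    }
    sort(b)
  })
  minimized <- unique(minimized)
  feats <- lapply(minimized, function(b) a[b])
  ord <- order(lengths(feats),
               vapply(feats, paste, character(1), collapse = "\r"))
  lapply(feats[ord], function(f) {
    hitfrac <- mean(rowSums(m[, match(f, a), drop = FALSE]) > 0L)
    score <- (1 - params$alpha) * (cost_a - cost_fn(f)) / cost_a +
      params$alpha * min(params$epsilon, hitfrac)
    new_reduct(f, method = "genetic", score = score)
  })
}
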