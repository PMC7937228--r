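---
title: "Rough-set rule learning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set rule learning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughrules)
```

## The model

A decision table 𝒟 = (U, A ∪ {d}) holds a finite universe U of objects,
features A, and a decision d ∉ A.  Every feature subset B ⊆ A induces an
equivalence relation — objects agreeing on all of B are indiscernible —
whose classes partition U.  A target set X ⊆ U (say, the cases) is
approximated by the union of classes contained in X (lower approximation:
certain members) and the union of classes intersecting X (upper
approximation: possible members); their difference is the boundary region,
and X is called *rough* when the boundary is nonempty.

Learning proceeds through the *decision-relative discernibility function*.
The table is first collapsed to one row per equivalence class of the full
feature set; each row carries the *generalized decision*, the set of
labels observed inside the class (encoded here as a sorted, pipe-joined
string such as `"autism|control"`).  For every pair of rows whose
generalized decisions differ as sets, the features on which they disagree
form one disjunctive clause.  A clause is emitted only when the decision
sets are unequal; two identical rows can never be decision-distinct
because they would have been merged into one class, so clauses are never
empty.  Duplicate clauses are retained as a multiset — they carry weight
in the greedy reducer — and absorbed (superset removal) only inside the
exhaustive minimizer, where absorption preserves the Boolean function.

A **reduct** is a minimal hitting set of this clause family, equivalently
a prime implicant of the conjunctive discernibility function: a minimal
feature subset discerning exactly the decision-distinct class pairs that
the full feature set discerns.  Overlaying a reduct over the equivalence
classes of its own indiscernibility relation yields rules: one rule per
class per decision label present in it, so boundary classes spawn one
rule per label.  Duplicate rules arising from overlapping reducts are
collapsed; voting is always over unique rules.

This package implements the *global* discernibility variant (one clause
family for the whole table).  Object-related (per-object) reducts, which
classic rough-set systems also offer and which tend to produce many short
rules, are a known alternative and are out of scope here; the practical
consequence is discussed under *Limitations*.

## Reducers

**Exhaustive.** All minimal hitting sets by branch-and-bound over clauses
after absorption, validated in the tests against a plain 2^|A| subset
scan.  The problem is NP-hard, so the enumerator refuses instances with
more than 20 features (configurable) and points to the heuristics.

**Johnson.** Greedy weighted set cover: repeatedly add the feature
maximizing the summed weight of uncovered clauses containing it.  Default
weights are 1 per clause *occurrence* (the multiset makes recurring
clauses count more); ties break on the lowest feature index so results
are reproducible.  Greedy choices can strand redundant features, so the
result is reduced to subset-minimality by reverse-order redundancy
elimination (on by default, flag-controlled).

**Genetic.** Bitstring-encoded subsets evolve under the fitness
f(B) = (1−α)·(cost(A)−cost(B))/cost(A) + α·min(ε, h(B)) where h(B) is the
fraction of clauses hit.  Every subset reaching hitting fraction ε enters
a keep-list, which is finally reduced to distinct subset-minimal hitting
sets.  The published description fixes only the fitness; the schedule is
this package's choice: α = 0.9, ε = 1, cost = cardinality, population 70,
200 generations, binary tournament selection, one-point crossover with
probability 0.6, per-bit mutation 1/|A|, elitism 2, keep-list 256.  These
values make recovery of *all* minimal reducts on small instances (≤ 4
minimal reducts, ≤ 8 features) reliable within seconds, which is what the
oracle tests demand.  With ε < 1 (supported, not default) returned sets
may hit only a fraction of clauses; minimization then leaves them
untouched.

## Rule statistics

For a rule with LHS support y (objects satisfying all conjuncts), RHS
support x (those also matching the decision), class size n_d, opposite
count n_o = N − n_d:

* coverage_RHS = x / n_d, coverage_LHS = y / n_d, accuracy = x / y.
  The LHS coverage deliberately divides by the class size (not N),
  matching the published definition even though it can exceed 1 for
  class-spanning rules; a table-wide denominator is a documented
  alternative the caller can compute as `supp_lhs / N`.
* Significance: the hypergeometric law P(X = x) =
  C(n_d, x)·C(n_o, y−x)/C(N, y).  The default reported value is the
  upper tail P(X ≥ x) — a point mass is not a significance measure —
  with `tail = "point"` retained for literal reproduction.  The family
  for multiple-testing correction is all rules of the model; Bonferroni
  is the default (protecting against the thousands of rules the genetic
  reducer can produce), Holm and Benjamini–Hochberg are available.
* Risk ratio: exposure = satisfying the LHS, outcome = the rule's class;
  rr = (x/y)/((n_d−x)/(N−y)) with log-normal CI and a normal-approximation
  *P* value; zero cells in the numerator ratio trigger a flagged 0.5
  continuity correction; y = N (everyone exposed) leaves the ratio
  undefined.  Multi-class tables use class-vs-rest throughout.
* Support sets: the explicit LHS/RHS object ids are stored per rule, so
  supporting patients can be retrieved, and the per-rule visualization
  payload can split objects into supporters / same-class non-supporters /
  other classes against the continuous pre-discretization values.

`recalculate_rules()` restates every statistic of a model against a
reference table — the standard follow-up to undersampling — keeping rules
that match nothing but flagging them vacuous (accuracy reported as 0).

## Discretization

Equal-frequency binning fits per-feature cut points at the empirical
quantile ranks k·m/b, placing each cut midway between the bracketing
order statistics.  Tied order statistics cannot be split — a value must
fall in exactly one bin — so ties merge bins; a feature with fewer
distinct values than bins collapses with a warning.  Bin labels default
to `"1".."b"` with optional aliases (e.g. low/medium/high).  Maps are
fitted on training data only and applied to test data with clamping to
the extreme bins; missing values are rejected at read time because every
formula above assumes total information vectors.

## Prediction, validation, imbalance

Votes are counted per object as the number of unique rules whose LHS it
satisfies, grouped by rule decision.  Per-class normalization divides the
counts by the class's mean/median/max count over the scored objects, its
rule count, or the root sum of squares; a nonpositive scalar falls back
to 1.  The prediction is the argmax, with ties broken to the first class
in training order (flagged) and objects firing no rule reported as
`unclassified` — counted as errors everywhere, a conservative choice.

Cross-validation is stratified (class proportions survive folding, which
the imbalance analyses need), fits discretization cuts on each training
part only, and reports per-fold and pooled accuracy plus a rank-based
(Mann–Whitney, midrank ties) AUC over pooled normalized scores of the
positive class — by default the lexicographically last label.

Undersampling builds ⌈n_maj/n_min⌉ balanced subsets: every minority
object plus a minority-sized draw from each larger class, the draws being
consecutive cyclic slices of one random permutation per class so each
subset samples without replacement *and* the union covers the class.
Sub-models are merged keeping unique rules, and statistics are restated
on the full table.  The merged model's **accuracy estimate** is the mean
of the sub-models' accuracies, each measured by a small internal CV
(default 5-fold) on its own balanced subset.  This is a deliberate and
important design point: with one-vote-per-unique-rule semantics, the
merged ensemble reproduces the plain model's vote-tie structure on null
data, so its held-out accuracy on an imbalanced test set stays near the
majority fraction; the quantity that undersampling genuinely repairs is
the model's own accuracy estimate, which the balanced evaluation frees of
majority bias.  `cross_validate()` therefore reports both: `mean_accuracy`
(held-out) and `model_accuracy` (the ensemble's balanced estimate).
AUC, computed from ranked scores, is insensitive to the imbalance either
way — which is exactly why it is the preferred metric here.

The permutation test shuffles labels n_perm times, reruns the full
cross-validated pipeline per shuffle, and uses the add-one estimator
p = (1 + #{null ≥ observed})/(1 + n_perm), so p is never 0 and a model
beating 100 shuffles reports p = 1/101 ≤ 0.01, for accuracy and AUC
separately.

## Synthetic data

The generator draws a standard-normal object × feature matrix Z and maps
it through the lower-triangular Cholesky factor of a user-specified
positive-definite covariance D = L·Lᵀ (identity, exchangeable(ρ), or an
explicit matrix), so rows carry the target covariance exactly in
expectation.  Class labels are assigned by largest-remainder rounding of
the requested proportions — deterministic counts, not Bernoulli draws —
because the imbalance experiments need exact ratios.  The class signal,
where requested, is a mean shift of `effect_size` SDs on the first
`n_informative` features for one designated class: the minimal
controllable mechanism enabling parameter-recovery tests.  What the
generator does *not* emulate: non-Gaussian marginals, feature
interactions (epistasis), batch structure, or the measurement noise floor
of real transcriptomics — so a green synthetic test establishes correct
mechanics and qualitative behavior, not field performance.

### Sizes chosen for the stochastic acceptance experiments

Neither the imbalance nor the calibration claim fixes the table sizes, so
they are this package's choices, made once on coverage grounds and not
revisited:

* *Imbalance experiment*: 500 objects, 5 features, 90/10 classes, two
  equal-frequency bins, 20 seeds.  Exact-cell rules only generalize to
  cells seen in training, so the world must keep the cell grid (2⁵ = 32)
  well covered by the balanced subsets (~90 objects) while leaving
  enough pure cells in the full table for a nonempty discernibility
  family; 32 cells at these sample sizes satisfies both, whereas 3 bins
  on 4+ features starves the sub-models (unclassified objects dominate)
  and 2–3 coarse features let every cell become boundary, which empties
  the clause family.  The undersampled arm runs 5 outer folds instead of
  10 purely for runtime; its reported quantity (the balanced sub-model
  average) does not depend on the outer folding.
* *Permutation calibration*: null arm 60 objects × 3 features, 19
  shuffles, 20 replicates (p-granularity 1/20 suffices to test
  uniformity above 0.05); strong arm 100 objects, all 3 features shifted
  by 2 SD, 100 shuffles, 3-fold CV — scaled to keep the suite inside its
  time budget.

## Numerical choices and degenerate inputs

* Deterministic everywhere: partitions order blocks by smallest object
  index; rules sort by decision, descending RHS support, descending
  accuracy, then the conjunct string; reducts sort by size then
  lexicographically; all stochastic steps take explicit seeds and derive
  per-fold/per-subset seeds inside 32-bit range.
* A single-class table yields an empty clause family; training on it is
  refused, and an empty family inside a CV fold (possible on shuffled or
  fully-boundary data) produces an empty model whose predictions are all
  `unclassified` — honest errors rather than a crash.
* Generalized labels use `"|"` as separator; class labels containing the
  pipe character are therefore not supported.
* `accuracy * supp_lhs == supp_rhs` holds exactly (integer counting);
  hypergeometric tails are computed by `phyper`, verified against
  exhaustive draw enumeration to 1e−12.

## Limitations

Rules condition on exact discrete cells, so models cannot score objects
whose cell was never seen in training (reported `unclassified`); with
many features this dominates unless the data are dense or the binning
coarse — the global-reduct variant has no mechanism for producing the
shorter, more general rules an object-related variant would yield.
Approximate reducts (ε < 1) are supported in the genetic reducer but not
wired into the default pipeline.  The co-prediction network's connection
score (support × accuracy summed over retained rules) is a documented
stand-in for the proprietary scores of external viewers; it is linear in
support and monotone in both inputs, which the tests pin down.
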