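# roughrules

Interpretable rule-based classification with rough sets.

`roughrules` learns transparent IF–THEN rule models from *decision tables*
— object × feature grids with one designated outcome column, the natural
shape of case–control omics data.  Instead of a black box it returns a list
of human-readable rules such as

```
IF g2 = low AND rf = yes THEN diagnosis = autism
```

each annotated with full statistics: support, coverage, accuracy, a
hypergeometric enrichment *P* value with multiple-testing correction, a
risk ratio with confidence interval, and the explicit ids of the objects
supporting the rule.

## The model in brief

For a decision system 𝒟 = (U, A ∪ {d}), any feature subset B ⊆ A induces an
*indiscernibility relation* whose equivalence classes partition U; a target
set X ⊆ U is approximated from below and above by the classes contained in
or intersecting X (lower/upper approximation, boundary region).  For every
pair of equivalence classes with different (generalized) decisions, the set
of features telling them apart forms one clause of the *discernibility
function*; a **reduct** is a minimal hitting set of these clauses — a
minimal feature subset that preserves all class distinctions.  Overlaying a
reduct on the equivalence classes yields the rules.  The package computes
reducts three ways:

* **exhaustive** — all minimal hitting sets (branch-and-bound with
  absorption; NP-hard, so capped at 20 features);
* **Johnson** — deterministic greedy weighted set cover;
* **genetic** — a GA over bitstring subsets with fitness
  `(1−α)·(cost(A)−cost(B))/cost(A) + α·min(ε, hit fraction)`.

Rule quality uses the hypergeometric law
`P(X = x) = C(n_d, x) C(n_o, y−x) / C(N, y)` where `y`/`x` are the LHS/RHS
supports and `n_d`, `n_o`, `N` the class and total object counts; the
upper tail `P(X ≥ x)` is the rule's enrichment *P* value.  Prediction is
by rule voting with optional per-class normalization (mean, median, max,
rule count, root-sum-of-squares) to correct rule-count imbalance.  Class
imbalance in the data is handled by undersampling ensembles: balanced
subsets whose models are merged (unique rules) and restated on the full
table.  A Cholesky-based generator produces synthetic decision tables with
controlled covariance, class proportions and effect sizes for validation.

## Worked example

The bundled toy autism table (8 equivalence classes, three genes and a
risk factor, boundary classes carrying both labels):

```r
library(roughrules)
tab2 <- fixture_tables()$table2

fam <- discernibility_family(tab2)
#> Discernibility family: 21 clause(s) over 4 feature(s), 8 classes

reducts <- enumerate_minimal_hitting_sets(fam)
#> Reduct {g2, g3} (exhaustive, score 2)
#> Reduct {g2, rf} (exhaustive, score 2)

model <- induce_rules(tab2, reducts)
#> Rule model: 12 rule(s), 2 class(es), trained on 8 objects
#>   rules per class: autism (6), control (6)
```

The two reducts say: gene 2 together with either gene 3 or the risk
factor discerns autism from control everywhere the full feature set does.
The top induced rules (LHS/RHS support, accuracy, raw and
Bonferroni-adjusted *P*):

```
              rule decision lhs rhs acc     p p_adj
  g2=low & g3=high   autism   2   2   1 0.357     1
g2=low & g3=medium   autism   2   2   1 0.357     1
    g2=low & rf=no   autism   2   2   1 0.357     1
   g2=low & rf=yes   autism   2   2   1 0.357     1
```

(with 8 objects nothing can be significant — the *P* value machinery is
exercised for real on larger tables).  On synthetic data with a genuine
class signal (150 objects, 3 correlated-free features, a 2 SD mean shift):

```r
dt <- synthesize_table(150, 3, n_informative = 3, effect_size = 2, seed = 7)
cross_validate(dt, pipeline_config(bins = 3), folds = 10, seed = 1)
#> 10-fold CV: mean accuracy 0.848, pooled accuracy 0.847, AUC 0.910

permutation_test(dt, pipeline_config(bins = 3), folds = 5, n_perm = 100, seed = 1)
#> Permutation test (100 shuffles): p[accuracy] = 0.0099, p[AUC] = 0.0099
```

The cross-validated model recovers the signal (AUC 0.91) and beats all
100 label shuffles (p = 1/101 ≤ 0.01).  Rule models export as
co-prediction networks (`build_network()`, `export_network()`) whose
edges connect feature=level conjuncts co-occurring in significant rules,
weighted by support × accuracy.

## Command line

```sh
Rscript -e 'roughrules::roughrules_cli()' synth --n 200 --features 5 \
    --proportions 0.9,0.1 --seed 1 --out table.csv
Rscript -e 'roughrules::roughrules_cli()' cv --in table.csv --id-column \
    --bins 2 --folds 10 --seed 1
```

Subcommands: `synth`, `train`, `cv`, `predict`, `permtest`, `export-net`
(see `?roughrules_cli`).

## Documentation

The methods vignette (`vignettes/rough-set-rule-learning.Rmd`) describes
the model, every tunable parameter, the synthetic-data generator and the
package's numerical design choices.
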