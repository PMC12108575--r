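---
title: "Ensemble feature selection with nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble feature selection with nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efscv)
```

## The problem

Rare-disease expression cohorts are small and wide: a NanoString-scale
miRNA panel measures hundreds of features on a few dozen subjects.
Any single feature-selection method run once on such data overfits —
it will happily find "discriminative" miRNAs in pure noise — and any
performance estimate computed on samples that influenced selection is
optimistic. `efscv` addresses both problems at once:

1. **Ensemble selection.** Four selector families with different
   inductive biases — recursive feature elimination (a wrapper around
   a linear model), random-forest Gini importance (embedded),
   L1-penalised logistic regression (embedded, sparsity-driven), and
   ANOVA-F k-best (a univariate filter) — vote on features. A feature
   enters a fold's consensus set only when at least
   `consensus_min_votes` (default 3 of 4) selectors back it.
2. **Nested cross-validation.** An outer loop partitions samples into
   non-overlapping validation folds (10% each by default, so 10 folds
   at N = 60). Inside each outer training set, an inner stratified
   k-fold loop (k = 5, an 80/20 inner split) runs the selector
   ensemble and benchmarks five classifier families. Features whose
   fold-level consensus persists across at least
   `fminimal_min_folds` (default 3) inner folds accumulate into the
   minimal signature; the most frequent inner-fold winner becomes the
   final model, which is retrained on each outer training set
   (restricted to the signature) and scored on the untouched outer
   validation fold.

The minimal signature plus the outer-fold metric distribution — not a
single point estimate — is the result.

## The procedure in detail

For a cohort of $N$ samples over $F$ features with binary labels:

* **Outer plan.** Validation-fold size is
  $p = \lfloor N \cdot \text{fraction} \rfloor$ and there are
  $\lfloor N / p \rfloor$ folds; samples are spread as evenly as
  possible (sizes differ by at most one) and, by default, stratified
  by class through largest-remainder apportionment, so every fold's
  class count is within one sample of its proportional share. At
  $N = 60$ and fraction $0.10$: 10 folds, each 54 train / 6
  validation. Stratification is not part of the original recipe but
  is on by default: with 60 samples, unstratified folds can produce
  single-class validation sets on which specificity is undefined.
* **Inner loop.** Each outer training set $T_i$ is split into $k$
  stratified folds. On each inner-train part $t_j$: the feature
  transform is fitted (on $t_j$ only), the four selectors each
  nominate features (a fixed budget of `n_select = 10` for RFE,
  RF-importance and k-best; natural sparsity for the LASSO), and the
  consensus vote is taken. All five classifiers are trained on $t_j$
  restricted to that consensus set and evaluated on $v_j$; the fold
  winner is the model with the best mean of the five metrics (ties:
  higher AUC, then roster order).
* **Signature accumulation.** Fold-level consensus sets are counted
  across inner folds; features present in at least
  `fminimal_min_folds` sets form the signature. Two printed readings
  of the original recipe exist — "backed by at least three
  algorithms" and "selected in at least three inner folds" — so both
  thresholds are implemented and composed by default
  (`consensus_mode = "both"`), with `"algorithms_only"` and
  `"folds_only"` exposing each reading alone.
* **Outer validation.** Per outer fold, the winning model is
  retrained on all of $T_i$ (transform refitted on $T_i$, features
  restricted to the signature) and evaluated on $V_i$. The report
  aggregates the $p$ outer evaluations as mean ± sd with a Student-t
  95% interval truncated to $[0, 1]$.

## Metrics

All metrics are computed in-package from first principles and are
cross-checked in the test suite against independent oracles:

* accuracy $= (TP+TN)/(TP+TN+FP+FN)$;
* sensitivity (recall, true positive rate) $= TP/(TP+FN)$;
* specificity $= TN/(TN+FP)$;
* F1 $= 2 \cdot \text{precision} \cdot \text{recall} /
  (\text{precision} + \text{recall})$ with precision $= TP/(TP+FP)$;
* AUC via the Mann–Whitney rank identity (ties at half weight),
  which equals trapezoidal ROC integration.

Empty denominators yield 0 by convention and are flagged in the
per-fold table and the report warnings. Reports carry an explicit
note that sensitivity is $TP/(TP+FN)$: the recall formula, which is
what the "true positive rate" label and the ROC construction require
(a formula sheet circulating for this recipe misprints it as
$TP/(TP+FP)$, which is precision).

## Design choices that were genuinely open

* **Signature scope.** The original recipe's flow accumulates one
  signature across *all* outer folds (`fminimal_scope = "global"`,
  the default here), which means each outer validation set has
  influenced selection through other folds' inner loops. That
  estimate is therefore labeled in the report as shared-signature.
  The alternative `"per_outer_fold"` accumulates strictly inside each
  outer training set and gives the leakage-free estimate; it is what
  the package's own null-calibration check runs, because on a
  label-independent cohort only that configuration is expected to sit
  at chance (the global scope measurably exceeds it — that is
  selection optimism, not a bug, and is why the distinction matters).
* **Fold-count arithmetic.** "Leave-p-out" here means p
  non-overlapping validation folds (p-fold style), not combinatorial
  $\binom{N}{p}$ leave-p-out — the latter would mean
  $\binom{60}{6} \approx 5 \times 10^7$ iterations rather than 10.
  When the fold size does not divide $N$, the remainder is spread one
  sample per fold from the first fold onward.
* **RFE base estimator.** Feature ranking uses an L2-penalised
  least-squares classifier on ±1 labels, solved in the dual (an
  $n \times n$ system), eliminating one feature per refit. With
  $n \approx 43$ inner-training samples this makes single-step
  elimination over 798 features cheap while keeping the canonical
  "linear-model coefficient magnitude" ranking. `ridge_lambda`
  defaults to 1.
* **Preprocessing.** Counts are transformed as $\log_2(x+1)$ followed
  by a per-feature z-score. The original recipe is silent on scaling;
  the LASSO and the SVM are scale-sensitive, so one uniform transform
  is applied for all selectors and classifiers, fitted on the
  training portion of every split and applied frozen to the held-out
  portion. Zero-variance training features map to 0.
* **Classifier defaults.** "Default hyperparameters" is read as the
  fitting library's defaults, pinned: `stats::glm` logistic
  regression; `randomForest` with 500 trees; `e1071::svm` with RBF
  kernel and cost 1 (decision values mapped monotonically to
  $[0, 1]$; AUC is rank-invariant, so no calibration is attempted);
  `xgboost` with `binary:logistic`, 100 rounds, depth 6, eta 0.3;
  and discrete AdaBoost (SAMME on ±1 labels) over depth-1 `rpart`
  stumps, 50 rounds, implemented in-package. Logistic fits on small
  separable folds trigger R's perfect-separation warnings; these are
  suppressed at the fit site since the ranked scores remain usable.
* **Tie-breaking.** Everywhere: descending score, then ascending
  feature ID (for elimination: the lexicographically larger twin is
  dropped). Model ties: higher mean AUC, then roster order. Total
  orders make runs byte-reproducible.
* **Empty consensus / empty signature.** If a fold's consensus is
  empty, the vote threshold is relaxed one step at a time (the k-best
  selector guarantees a nonempty floor); if no feature reaches the
  fold threshold, `fminimal_min_folds` is relaxed the same way. Every
  relaxation is recorded in the report warnings.
* **Best-model rule.** Within an inner fold the winner is the best
  mean of the five metrics; across folds the final model is the most
  frequent winner (`model_selection_rule = "frequency"`), with
  `"mean_performance"` as the alternative.

## The synthetic cohort generator

Real cohorts of this kind are rarely public, so the package ships a
generator that emulates their shape and statistical structure:
negative-binomial (Gamma–Poisson) counts with feature-specific base
means drawn log-uniformly over $2^4$–$2^{10}$ and a shared dispersion
of 0.3 (counts are overdispersed, as hybridization-count data are),
798 features over 31 case and 29 control samples by default, and a
planted set of 10 informative features whose case-class mean is
shifted by a log2 fold change of 2, half up / half down — resembling
the mixed up/down regulation reported for real signatures. Defaults
were chosen once to mirror the published cohort's shape; the fold
change and dispersion are "clearly detectable but noisy" values a
simulation study of this design would typically use.

What the generator does **not** model: positive/negative control
probes, batch effects, library-size or ligation biases, feature-
specific dispersions, or correlation between miRNAs. Passing the
recovery and calibration checks therefore demonstrates that the
pipeline's logic is sound (it finds planted signal, it does not
invent signal from noise, it does not leak), not that any particular
real cohort will yield a 10-feature signature with these metrics.

```{r generator, eval = FALSE}
cohort <- simulate_cohort(synthetic_spec(seed = 1))
report <- run_pipeline(cohort$matrix, cohort$labels,
                       pipeline_config(random_seed = 1))
glance(report)
autoplot(report)
```

## Numerical conventions and degenerate inputs

* ANOVA F with zero within-group variance: 0 when the group means are
  equal, `Inf` when they differ (a perfect separator outranks
  everything finite, which is the intended ordering).
* Metrics with empty denominators are 0 and flagged.
* Single-fold aggregates report sd 0 and a degenerate (point)
  interval, flagged in `degenerate_ci`.
* Matrix round trips are written at 12 significant digits.
* Every stochastic component (fold shuffles, forests, boosting,
  generator) derives its seed deterministically from the master seed,
  so a report is a pure function of (input files, config, seed);
  `report.json` contains no timestamps and reruns are byte-identical.

## Problem sizes used in the package's own checks

The end-to-end checks run the full 798 × 60 study shape (planted
recovery, null calibration, and byte-level determinism, about a
minute per pipeline run); unit tests exercise the same code paths on
40–120-feature cohorts. Property suites use 500 random AUC instances
(n ≤ 12) against a brute-force concordance oracle, 200 ANOVA-F
instances against the squared pooled-t identity, and 1000 random
draws each for consensus counting and fold-plan invariants.

## Known limitations

* Binary labels only; multi-class tasks are out of scope.
* Normalization (e.g. NanoString QC/batch normalization) is assumed
  done upstream; the pipeline consumes a normalized matrix.
* The global-scope outer estimate is intentionally faithful to the
  original flow and therefore optimistic; use
  `fminimal_scope = "per_outer_fold"` when an unbiased estimate is
  the goal.
* Selector budgets (`n_select`) are fixed per fold rather than tuned;
  the original recipe does not state them, and fixed budgets keep
  votes comparable across selectors.
* No hyperparameter search anywhere, by design.
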