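---
title: "Decision strategies and calibration for parallel classifier ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision strategies and calibration for parallel classifier ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calibens)
```

## Setting

A parallel (bagging-style) ensemble trains m base classifiers on
overlapping subsets of the training data — here, the models saved from m
cross-validation folds — and combines their predictions on a common test
set. Each base model emits a softmax row per sample: pseudo-probabilities
over K classes. The package evaluates three strategies for turning m such
rows into one decision:

* **Majority vote** — each model casts its argmax class as a hard vote;
  the most-voted class wins. Probabilities are discarded, so ROC AUC and
  calibration error cannot be computed for this strategy.
* **Unweighted average** — the mean of the m softmax rows; decision by
  argmax of the mean.
* **Weighted average** — a convex combination with performance-derived
  weights (next section).

The motivating application is three-class dementia detection (CN / MCI /
AD) from structural MRI, where cohorts are small and imbalanced and where
the clinical usefulness of a probability output depends on calibration as
much as on discrimination.

## The rank-squared weighting scheme

Weights come from the base models' *validation* balanced accuracies
`bacc_1..bacc_m` — performance on held-out fold data, never on the test
set. With ranks 1..m ascending in balanced accuracy and
`beta = min(bacc)`:

    alpha_j = (bacc_j - beta + 1) * rank_j^2
    w_j     = alpha_j / sum(alpha)

Two design points matter. The additive constant 1 guarantees
`alpha_j >= 1 > 0`, so the weakest model still contributes (its alpha is
exactly 1). The squared rank is what separates the models: subtracting
`beta` alone would give nearly equal weights whenever validation
accuracies are close, whereas `rank^2` spreads them roughly 1 : 4 : 9 :
16 : 25 before the accuracy-difference factor.

```{r}
tidy(ensemble_weights(c(0.485, 0.704, 0.635, 0.734, 0.783)))
```

Deterministic corner cases, chosen once and kept:

* **Rank ties** are broken by input position (the earlier model gets the
  lower rank). Ties never arise in realistic validation tables, and a
  positional rule is deterministic without a seed. A documented
  consequence: models with *equal* balanced accuracies still receive
  rank-squared-proportional (unequal) weights.
* **Argmax and vote ties** are broken by the lowest class index, applied
  identically in `hard_labels()` and `majority_vote()` so the two stages
  cannot disagree on tie handling; tie counts are reported.
* Weighted-average inputs are combined as raw softmax rows. Since each
  row already sums to 1 and the weights are convex, the output is
  normalized by construction and no per-sample renormalization step is
  needed (or applied).
* Weights are carried at full precision; tables round to 3 decimals for
  display only.

## Detection metrics under imbalance

With a roughly 55/34/11 class split, plain accuracy is dominated by the
majority class. The suite therefore centres on:

* **Balanced accuracy** — the unweighted mean of per-class recall. A
  constant single-class predictor scores exactly `1/K` regardless of the
  imbalance, which makes degenerate classifiers easy to spot.
* **Weighted one-vs-rest metrics** — precision, recall, specificity, and
  F1 computed per class against the rest, then averaged with weights
  proportional to true-class support (the convention of standard
  classification reports; weighted recall then equals plain accuracy,
  which the tests exploit as an algebraic cross-check). Undefined cells —
  a class never predicted has no precision — score 0 with a warning, the
  conservative convention.
* **One-vs-one ROC AUC** — for each unordered class pair, samples are
  restricted to the two classes, both directed AUCs are computed from the
  two single-class probability columns (Mann–Whitney rank statistic, ties
  at 1/2) and averaged; the result is the mean over all `K(K-1)/2` pairs,
  so rare-class pairs count equally rather than by prevalence.

Aggregated ROC curves (`aggregate_roc()`) linearly interpolate each
bootstrap-replicate, one-vs-one-binarized curve onto a fixed 101-point
false-positive-rate grid anchored at (0,0) and (1,1), then take pointwise
means and percentile 2.5/97.5 bands. At the default settings — 100
bootstrap replicates times 3 class pairs — 300 curves enter one band.

## Calibration: binned ECE and reliability diagrams

Calibration is summarized by top-label confidence binning: each sample
contributes its maximum class probability (confidence) and whether its
argmax was correct. Bins partition `[0, 1]`; per non-empty bin b the mean
confidence `conf_b` is compared with the accuracy `acc_b`, and

    ECE = sum_b (n_b / n) * |acc_b - conf_b|.

Defaults: 15 equal-width bins (the common fixed-bin convention), each
interval left-closed/right-open with the last closed so confidence 1.0 is
counted. A quantile scheme (edges at confidence quantiles, duplicates
collapsed) is available since bin placement may also be optimized rather
than fixed. Empty bins carry zero weight; nothing is imputed.

Top-label binning was chosen over per-class variants because it is the
standard reliability-diagram construction for multi-class networks and
matches how confidence is used at decision time; a variant that
conditions the bar heights on correct detections only was considered and
rejected as non-standard (it cannot detect over-confidence on errors,
which is exactly the clinically dangerous case).

Hard-label ensembles are rejected by `reliability()`/`ece()` with an
explicit error rather than silently treated as one-hot probabilities:
votes are not confidences.

## Resampling and statistical comparison

* **Bootstrap**: the test population is resampled with replacement R =
  100 times; each metric's replicate values are summarized by their mean
  and percentile 95% CI (2.5/97.5 percentiles — chosen as the simplest
  assumption-free interval). Replicates missing a class, possible for a
  rare class, are redrawn up to 100 times, then the run aborts.
  The same seeded index sets are reused for every model and strategy in
  an experiment, so comparisons share resampling noise.
* **z-test**: two strategies are compared by
  `z = (mean_a - mean_b) / sqrt(s_a^2/R_a + s_b^2/R_b)` with `s` the
  replicate standard deviation, two-tailed normal p-values, and the usual
  star codes (`***` p<0.001, `**` p<0.01, `*` p<0.05, `ns`). Using
  `s^2/R` per arm treats the bootstrap replicates as the sampling
  distribution of the mean. Comparisons are independent-sample by
  default; p-values are reported raw (no multiple-testing correction),
  matching the usual presentation of such tables, and can be corrected
  externally if desired.
* **Comparison tables**: within a model group and metric, the best mean
  (maximum for detection metrics, minimum for ECE) is the reference row;
  all others are z-compared against it. Base-model groups append an
  "Average of means" row.
* **Chi-square**: cohort contingency tables (e.g. sex by diagnosis) use
  Pearson's test without continuity correction via `stats::chisq.test()`.

## The synthetic generator

Real inputs to this pipeline are CNN softmax outputs on a held-out
imaging cohort. The generator replaces both with a transparent
statistical stand-in:

* **Cohort**: n = 651 subjects, class mixture proportional to
  361 : 222 : 68 (CN : MCI : AD), per-class female proportions
  63.4% / 45.0% / 39.7%, per-class normal ages 69.5 ± 6.7 / 71.9 ± 7.6 /
  74.4 ± 7.9 years, clipped to 50–90 and rounded to whole years. These
  defaults mirror a typical research-cohort composition for this task
  and are fixed; they are conditions, not tuning knobs.
* **Split**: joint stratification by diagnosis × sex × five-year age bin
  (bins `<=64`, 65–69, 70–74, 75–80, `>=81`, open-ended extremes), 80/20
  with largest-remainder rounding so every stratum's test share is
  within one subject of the target. Joint (rather than marginal)
  stratification was chosen because it is the stronger guarantee and is
  what "stratified by A, B, and C" most naturally means; singleton
  strata go to train so the test set keeps class coverage.
* **Predictions**: for sample i with true class k, model j draws logits
  `signal_j * onehot(k) + N(0, 1)` per class and emits
  `softmax(logits / temperature_j)`. The two dials are independent:
  `signal` moves accuracy from chance (0) to near-perfect (≈10), while
  `temperature` reshapes confidence at an unchanged decision rule
  (< 1 over-confident, > 1 under-confident). This logit-noise model was
  chosen precisely because it separates the two axes the evaluation
  suite measures. The default bank of five models
  (signal 0.6–2.2, temperature 0.5–1.6) is heterogeneous in both,
  mimicking fold-to-fold variability.

Per-model randomness derives deterministically from the master seed and
the model index, so the whole bank — cohort, split, predictions — is
bit-reproducible, and validation-fold predictions are obtained from the
same bank with a fixed seed offset.

What passing tests on this generator do show: the combiners, metrics, and
resampling machinery are correct (they match independent brute-force
oracles to 1e-12), the calibration metric responds monotonically to
injected miscalibration, and detection metrics respond monotonically to
injected signal. What they do not show: anything about real MRI-derived
softmax outputs, whose errors are correlated across folds, class- and
covariate-dependent, and not Gaussian in logit space. In particular the
generator's independent per-model noise makes averaging ensembles look
better, and more under-confident, than correlated real base models
typically are.

## Numerical choices and problem sizes

* Probability rows must sum to 1: deviations above 1e-4 are rejected as
  data errors; deviations in (1e-6, 1e-4] are renormalized with a
  warning (float round-trip noise); smaller deviations pass untouched.
* Prediction files are written with 17 significant digits and read with
  a correctly-rounded parser, so a write/read round trip is exact to
  below 1e-12.
* Alignment between models is by sample id, never by row position;
  class columns are re-indexed by name against the first model's order.
* ROC interpolation uses `ties = max` so vertical ROC segments resolve
  to their upper point; degenerate one-point curves reduce to the
  (0,0)–(1,1) anchors.
* The test suite runs its oracle-equivalence loops on 1000 random
  instances of 6–14 samples, its Monte-Carlo dial-recovery checks on 100
  seeds at n = 2000, and full experiments at n = 300–651 with R = 100 —
  sizes chosen to exercise every code path while keeping the default
  suite around a minute.

## Known limitations

* No recalibration (temperature scaling, Platt, isotonic) — the package
  measures calibration, it does not repair it.
* No boosting or stacking: combination is strictly at decision level
  over independently trained models.
* The z-test treats bootstrap replicate distributions as sampling
  distributions of the means; with only R = 100 replicates the normal
  approximation is adequate for the headline metrics but p-values very
  close to thresholds should not be over-read.
* ECE depends on the binning; the one-bin-width disagreement between
  fixed and quantile schemes observed in the tests is inherent to binned
  estimators, not a defect.
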