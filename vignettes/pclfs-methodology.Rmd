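---
title: "Selecting minimal feature subsets with near-maximal F1: methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal feature subsets with near-maximal F1: methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Wrapper feature-selection methods score many candidate feature subsets with a
classifier and keep the one with the best score. On real data the score curve
is typically flat near its maximum: there are much smaller subsets whose score
is lower by an amount nobody cares about. When features are expensive to
measure — sensors, assays, patient examinations — the maximum-score subset is
rarely the subset you actually want. `pclfsx` implements a wrapper selector
whose output is the *smallest* subset whose score is within a user-chosen
budget of the maximum, together with the machinery needed to study its
behaviour: a class-imbalance-aware evaluation (minority-class F1), SMOTE
rebalancing, a recursive-feature-elimination (RFE) baseline, a synthetic-data
generator with known ground truth, and a replicated simulation harness.

## The selection procedure

### Ranking by principal-component loadings

For a training matrix with $n$ features, features are ranked once, before any
classifier is involved, by

$$\mathrm{score}_k = |L_{1k}| + |L_{2k}|,$$

where $L_{1}$ and $L_{2}$ are the loading vectors (unit-norm eigenvector
coefficients) of the first two principal components. Columns are z-scored
first by default, so this is correlation-matrix PCA; loadings are otherwise
scale-dependent and mixed measurement scales would dominate the ranking
(`standardize = FALSE` is available for data already on one scale). The
intuition: features that carry the dominant joint structure of the data load
heavily on the leading components, while isolated noise features spread tiny
loadings across many components. Eigenvector signs are arbitrary, and
irrelevant here because only absolute values enter; exact score ties are
broken by ascending column index so the ranking is deterministic.

The PCA is computed on the training partition only (after SMOTE, if SMOTE is
requested) — test rows never influence the ranking.

### The sequential F1 grid and the maximum rule

Features are added one at a time in ranking order. At each size
$i = 1, \dots, n$ a fresh classifier is fitted on the first $i$ ordered
features and scored on the held-out test partition by minority-class F1,
giving the grid $g = (g_1, \dots, g_n)$. The original rule (PCLFS) keeps

$$n_{\mathrm{pclfs}} = \min \{\, i : g_i = \max(g) \,\},$$

the smallest size attaining the maximum.

### The gradient-threshold extension

The extension looks below the optimum for a cheaper stopping point. A size
$j < n_{\mathrm{pclfs}}$ is a *candidate* when it is a strict local maximum
of the grid, $g_j > \max(g_{j-1}, g_{j+1})$. Requiring a local maximum is
what makes the rule well-defined: if a neighbour scores higher, the
neighbour — not $j$ — is the sensible stopping point. Each candidate is
joined to the optimum by a line whose gradient

$$\mathrm{gradient}_j = \frac{g_{n_{\mathrm{pclfs}}} - g_j}{n_{\mathrm{pclfs}} - j}$$

is the F1 given up per feature saved. The user states a total budget: the
maximum tolerable F1 reduction (argument `tolerance`, default 0.05). Spread
over the dataset's $n$ features this gives the per-feature threshold

$$t = \frac{\mathrm{tolerance}}{n},$$

and the proposed size is the smallest candidate with
$\mathrm{gradient}_j < t$. Two points deserve emphasis:

* $n$ is the **total** feature count, not $n_{\mathrm{pclfs}}$: with
  `tolerance = 0.05` a 44-feature dataset gets $t = 0.0011$ and a 30-feature
  dataset $t = 0.0017$. A fixed numeric cut-off would discount one feature
  and twenty features equally; dividing by $n$ prices the loss per feature
  and keeps the rule consistent across dimensionalities.
* all inequalities are strict. Plateau points (a candidate tied with a
  neighbour) fail the local-maximum test and drop out silently; a gradient
  exactly equal to $t$ does not qualify. With `tolerance = 0` nothing can
  qualify, so the extension reproduces PCLFS exactly.

If no candidate qualifies — including the degenerate case
$n_{\mathrm{pclfs}} = 1$ — the method falls back to the PCLFS result
(`fallback = TRUE`). The construction guarantees, algebraically and on every
run,

$$g_{n_{\mathrm{pclfs}}} - g_{n_{\mathrm{proposed}}} \le
  t \,(n_{\mathrm{pclfs}} - n_{\mathrm{proposed}}) \le \mathrm{tolerance}.$$

Boundary convention: at $j = 1$ there is no left neighbour, and we treat it
as $-\infty$, so an initial peak can qualify. The alternative (excluding
$j = 1$) would forbid single-feature answers, which is exactly the regime
the method exists for; this was a genuinely open choice and we document it
here rather than hide it.

### From size to subset

The proposed *size* comes from the grid; the proposed *subset* comes from the
classifier. The model refitted on the $n_{\mathrm{pclfs}}$ active features
supplies importance scores (absolute coefficients for linear models,
impurity-based importance for trees and ensembles), and the subset is the
$n_{\mathrm{proposed}}$ highest-importance features among the active ones,
ties broken by ranking position. We read "use the importance scores" as
selection by importance rather than truncation of the ranking prefix; the
prefix behaviour is retained as `subset_rule = "prefix"` for users who want
the purely sequential interpretation. The two coincide whenever importance
and ranking order agree, and the reported F1 on the proposed subset always
comes from a fresh refit on exactly that subset.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tolerance` | 0.05 | Maximum tolerable total F1 reduction (dimensionless, same scale as F1). The only parameter a user must think about; domain cost of a feature vs. a point of F1. |
| `classifier` | `"logit"` | Model family driving the grid and importances: `logit`, `svm_linear`, `decision_tree`, `random_forest`, `gbm`. The ranking is classifier-independent. |
| `test_fraction` | 0.25 | Held-out fraction for the grid (75/25 stratified split). |
| `smote` | `FALSE` | Rebalance the *training* partition by SMOTE before ranking and fitting. Test rows are never resampled — oversampling after evaluation-set construction would leak synthetic copies of test points. |
| `k_neighbors` | 5 | SMOTE neighbourhood size; reduced with a warning when the minority class is smaller. |
| `standardize` | `TRUE` | Correlation- vs covariance-matrix PCA for the ranking. |
| `subset_rule` | `"importance"` | Final subset by importance, or `"prefix"` truncation. |

Threshold sensitivity: for highly imbalanced data the F1 grid is noisier
(fewer minority test cases), so a larger `tolerance` achieves comparable
reductions; the budget is deliberately user-defined rather than calibrated
automatically.

## The synthetic-data generator

`simulate_binary_data()` emulates the simplest non-trivial study design:
two classes, one Gaussian cluster per class, a known set of informative
features, the rest independent standard-normal noise, and a configurable
imbalance rate with deterministic class counts
(majority `= round(n * w)`, minority the remainder).

The informative block is generated in a latent space where the class
centroids sit at $\pm\,\mathrm{class\_sep}/\sqrt{k}$ on each of the $k$
informative axes and is then passed through a random full-rank linear map
with unit-norm columns. The map preserves the Mahalanobis separation —
exactly $2\,\mathrm{class\_sep}$ between centroids for any $k$ — so
`class_sep` is a single interpretable knob, while the observed informative
features become mutually correlated with several high-variance directions.
That covariance structure matters: with strictly independent informative
columns the class signal spans a single direction, the second principal
component is pure noise, and a two-loading ranking criterion is handicapped
by construction. Real multivariate data, and the standard generators used in
feature-selection benchmarks, have correlated informative structure; the map
reproduces it without introducing redundant (rank-deficient) or repeated
features. Per-feature marginal signal varies randomly across informative
features, which is also realistic: some informative features are individually
weak and only useful jointly.

What the generator does **not** emulate: label noise, heavy tails,
categorical features, multiple clusters per class, and redundant feature
copies. Simulation results therefore show that the method recovers
informative sets under clean Gaussian geometry with known ground truth; they
do not certify behaviour under gross model misspecification, and on real
data the "informative set" is unobservable — there the method's output is
judged by its F1-vs-size trade-off only.

## The baselines and the harness

RFE is implemented in its standard form: drop the `step` least-important
features per iteration (importance from a fit on the full training data),
score every visited size by stratified k-fold cross-validated F1, keep the
best size (ties to the smaller subset). Defaults — step 1, 5 folds, F1
scoring — follow common practice.

`run_scenario()` sweeps the number of informative features, runs independent
replicates (replicate $r$ of sweep value $k$ uses seed
`base_seed + r + 100000 k`-indexed offsets, so any cell can be re-run in
isolation), and aggregates per-method means, standard deviations and best
values of F1, error rate, subset size, feature-selection TPR
($|S \cap I|/|I|$) and per-feature correct percentage
($100\,(TP + TN)/n$; the per-feature accuracy reading of "correct
percentage" — it is labelled explicitly in all outputs so an alternative
definition can be swapped in). Replicates whose split degenerates are
skipped with a warning and excluded from denominators, never silently
zero-filled.

Problem sizes in the shipped tests and the acceptance script are chosen to
make each property measurable while keeping a full run in tens of seconds:
grids and SMOTE contracts on hundreds of samples, ranking-recovery and
feature-recovery properties at 1,000 samples with 30 features and 20
seeds/replicates, the gradient-rule equivalence on 1,000 random grids
against a brute-force enumerator.

## Numerical choices and degenerate inputs

* Grid indices are 1-based everywhere a user sees them, matching the
  $g_j$ notation above.
* Exact ranking-score ties break by column index; scores are rounded to 8
  significant digits first so that floating-point noise cannot reorder
  genuinely tied columns (e.g. duplicated features).
* A constant column would make z-scoring divide by zero; it is divided by 1
  instead, with a warning, and ends up ranked by its (zero) loadings.
* Logistic fits on separable subsets produce convergence warnings by design;
  they are suppressed, as the fitted class boundary — not the coefficient
  scale — is what the grid consumes. Aliased coefficients (`NA`) count as
  zero importance.
* `smote()` requires at least two minority rows; identical minority points
  interpolate to themselves. Already-balanced data passes through untouched.
* All stochastic steps (generation, splitting, SMOTE, tree ensembles) are
  seed-controlled; derived seeds are small additive offsets of the user's
  seed.

## Known limitations

* Binary classification only; the minority class must be coded 1.
* The grid costs one classifier fit per feature; for very wide data
  (thousands of features) a coarser grid would be needed, which the
  sequential definition does not currently provide.
* The ranking uses exactly two components. Data whose informative structure
  is spread across many weak components will rank poorly — visible in the
  generator when informative columns are made independent.
* F1 is the only built-in grid score. The scoring hook is internal by
  design; alternative metrics would change the meaning of `tolerance`.
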