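---
title: "Predicting tumor purity with boosted-tree ensembles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tumor purity with boosted-tree ensembles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(puriboost)
```

## The problem and the model

Bulk tumor samples are mixtures: cancer cells plus a stromal compartment of
immune cells, fibroblasts and vasculature. The fraction of cancer cells —
tumor purity — is both a confounder for expression analyses and a quantity
of biological interest. Because stromal genes contribute expression in
proportion to the stromal fraction, purity leaves a strong, largely monotone
footprint in the transcriptome, and can be *predicted* from expression
alone once a training set with purity labels (typically copy-number-derived
consensus estimates) is available.

puriboost frames this as bounded-response regression. Observed purities
$y_i \in [0,1]$ are transformed to the real line,

$$ z_i = \log \frac{y_i}{1 - y_i}, $$

after reassigning boundary values ($1 \to 0.9975$, $0 \to 0.0025$) so the
logit is finite, and least-squares gradient-boosted regression trees are fit
to $z$. Predictions are mapped back with the inverse logit, which guarantees
$\hat y \in (0,1)$ — the reason for working on the logit scale at all, since
an untransformed regression can predict outside the unit interval.

### The ensemble of ensembles

A single boosted model on $p \gg n$ expression data is itself an ensemble of
trees, but its gene ranking is noisy: each tree sees only a random subset of
genes, so an informative gene can be under-used by chance. puriboost
therefore repeats $K$-fold cross-validation $R$ times (defaults $R = 100$,
$K = 10$): each repetition shuffles the training samples with its own
derived seed and cuts the shuffled order into $K$ contiguous, near-equal
blocks; one model is fit per (repetition, fold) on the $\approx 90\%$
partition, giving $M = R \times K$ models (1000 at full scale). The final
predictor is the *bagging average*: every model predicts on the logit scale,
each prediction is inverse-logit transformed, and the per-sample mean of the
$M$ original-scale values is reported.

Whether the averaging should happen before or after the inverse logit is
genuinely open; both keep predictions inside $(0,1)$. We average on the
original scale by default — it matches the order in which the transform and
the average are naturally described and makes the final value an ordinary
mean of valid purities — and expose `avg_scale = "logit"` in
`predict()` for the other reading. The two differ only slightly because the
inverse logit is near-linear over the mid-range where most predictions fall.

### Boosting configuration

`gbm_config()` defaults are the tuned pan-cancer parameter set:

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.05 | shrinkage per tree |
| `max_depth` | 4 | tree depth (shallow trees suit boosting) |
| `min_leaf_weight` | 1 | minimum leaf weight |
| `colsample_per_tree` | 0.65 | fraction of genes per tree |
| `subsample_per_tree` | 0.85 | fraction of samples per tree |
| `max_trees` | 5000 | boosting-round cap |
| `early_stop_patience` | 5 | rounds without improvement before stopping |

Early stopping needs a monitored error. Monitoring the *training* RMSE of a
least-squares boosted model almost never stops — training error decreases
essentially monotonically — so a patience of five rounds is only meaningful
against held-out data. We therefore monitor the fold's held-out 10% by
default and expose `monitor = "training"` for the literal alternative
reading.

`grid_search()` re-tunes these parameters by single-repetition $K$-fold
cross-validation, scoring by mean validation RMSE on the original purity
scale; ties break toward the smaller `learning_rate × max_trees` product,
then the smaller depth. The default grid is a compact 24-point lattice
around the tuned set (learning rate × depth × column-sample × row-sample);
a full-scale search over thousands of combinations is out of scope for a
package and the tuned defaults are shipped instead.

Two numerical choices worth noting: trees are grown with the histogram
split-finder at 64 bins per gene (`tree_method = "hist"`, `max_bin = 64`),
which on expression matrices reproduces exact-split accuracy at a fraction
of the cost; and all model fitting is single-threaded with one derived seed
per model (a master seed → per-repetition shuffle seeds → per-model learner
seeds ladder), which makes the full pipeline bitwise reproducible.

## Importance aggregation and marker panels

Within one model, gene $g$'s importance is its normalized total split gain

$$ S_{g\bullet} = \frac{\sum_t S_{gt}}{\sum_t \sum_{g'} S_{g't}}, $$

where $S_{gt}$ is the gain contributed by splits on $g$ in tree $t$ (the
learner's "gain" importance, which weights each split by the observations it
covers). Scores are nonnegative and sum to one per model; a gene never used
in a split scores exactly zero. puriboost extracts $S_{gt}$ from the trees
actually kept after early stopping, so importance and predictions describe
the same model.

Across the ensemble, a gene is **eligible** only if its score is strictly
positive in *all* $M$ models — a stability filter that discards genes whose
usefulness depends on a particular partition. Genes are ranked within each
model (descending score, average ranks on ties, so all-zero genes share the
bottom rank), and eligible genes are ordered by their **median rank** across
models. Ordering by the median (or mean) of the *scores* instead is
available via `rank_stat`; the two orderings agree at the top of the list in
high-signal settings, which the test suite asserts on synthetic data, but
median-rank is the default because rank aggregation is insensitive to a few
models assigning outlying score magnitudes. Remaining ties break by
descending mean score, then gene symbol, so output is deterministic.
`top_k_panel()` takes the first $k$ — ten at full scale, giving the shipped
`purity_marker_panel`.

`restrict_and_retrain()` repeats the *entire* pipeline — including a fresh
grid search — on a panel's columns only, because a ten-gene model prefers
different tuning than a 17,000-gene model.

## The permutation test

To check that predictive performance is not an artifact of the pipeline's
flexibility, `permutation_test()` permutes the *training* purities uniformly
at random, refits the (reduced-scale) ensemble, predicts the untouched test
set, and records the test statistic (Pearson r by default). With $B$
permutations the empirical p-value is

$$ p = \frac{1 + \#\{b : r_b \ge r_{\mathrm{obs}}\}}{B + 1}, $$

the add-one form, so $p > 0$ always and significance at small $B$ is not
overstated. Permuting only the training response is the standard
label-permutation null for supervised pipelines: it preserves the expression
covariance structure while destroying the expression–purity link.

## The synthetic benchmark

Real training data at scale (thousands of samples with copy-number purity
labels) cannot ship with a package, so all testing runs on a generative
model that mimics the features the method exploits:

* purity $p_i \sim \mathrm{Beta}(2,2)$ clipped to $[0.01, 0.99]$ — broad,
  interior-supported, like observed purity distributions;
* gene baselines $\mu_g \sim U(2, 10)$ on the log2 scale;
* a minority of planted stromal *marker* genes gains
  $\mathrm{effect} \times (1 - p_i)$, i.e. decreases monotonically with
  purity, exactly the immune-gene anti-correlation seen in tumors;
* per-tumor-type batch shifts $\delta_{tg} \sim N(0, 0.5)$ over 3 types and
  additive noise $\varepsilon \sim N(0, \sigma)$.

The signal is additive on the log2 scale, keeping the marker–purity
relationship monotone and interpretable; the count-scale mixture is
exercised separately by the single-cell path (below). Benchmark defaults
(600 samples, 2000 genes, 20 markers, effect 2, noise SD 0.5, 3 types) are
chosen so that markers are clearly but not trivially detectable — per-marker
correlation with purity around $-0.6$ — at problem sizes a single CPU
handles in minutes; where no external value dictated a parameter
(`type_shift_sd = 0.5`), we fixed one realistic value once. What passing
tests show is that the pipeline recovers planted monotone signal under batch
structure and noise; what they cannot show is robustness to real-data
pathologies the generator omits — outlying purity labels, platform effects,
correlated gene modules, or single-cell dropout and overdispersion.

`simulate_cells()` draws each cell's type as Bernoulli(purity) and its
counts as Poisson around a cancer or stromal rate profile; the realized
cancer-cell fraction is the recorded ground truth, matching how purity is
measured in annotated single-cell studies. `simulate_bulk_counts()` draws
reference bulk counts around the purity-weighted mixture of the same
profiles — the expectation of aggregating that many cells.

## Pseudo-bulk harmonization

`aggregate_to_bulk()` sums raw counts per gene over each sample's cells.
`merge_common_genes()` intersects gene sets exactly (case-sensitive symbol
match — silent aliasing is worse than a smaller intersection) and stacks
samples. `median_center_normalize()` computes each sample's median
expression, takes the median of the *reference* samples' medians as the
target $c$, brings every sample's median to $c$, then applies
$\log_2(\text{count} + 1)$. Whether "centering on the median of medians"
means an additive or a multiplicative adjustment, and on which scale, is
ambiguous; we default to multiplicative rescaling on the count scale
($\times\, c/\mathrm{median}_i$), because counts stay nonnegative before the
log — additive centering of raw counts can produce negatives — and expose
`method = "additive_log"` (additive centering of per-sample medians of
$\log_2(\text{count}+1)$) for the other reading. Both maps are monotone
within each sample. An even-sized median is the midpoint of the two central
values; a sample with median zero is an error naming the sample rather than
a silent division by zero.

## Degenerate inputs, tolerances, tie-breaks

* `log2_floor_transform()` refuses already-log2 input (scale flag), so the
  flooring rule `log2(max(v, 1))` is applied exactly once.
* `filter_genes()` removes genes with any missing value or zero variance;
  if everything is removed, that is an error.
* Duplicate samples per patient keep the lexicographically smallest sample
  ID — deterministic where any rule would do.
* Train/test splits take `round(fraction × n)` training samples; at
  `fraction = 2/3` this is the closest integer, with the remainder as test.
* A fold whose training partition has a constant target is skipped with a
  warning (reducing $M$) rather than aborting a long run; an ensemble where
  *every* fold is degenerate errors.
* The boundary constant 0.9975 is fixed, not recomputed from the data at
  hand, so transforms are reproducible across datasets; the reassignment is
  applied symmetrically at both boundaries.
* Logit/inverse-logit round-trip to within $10^{-12}$ on
  $[0.0025, 0.9975]$; importance normalization is exact to $10^{-9}$ per
  model column.

## Problem sizes used by the test suite

Tests and the acceptance script run reduced but structurally faithful
versions of the full-scale procedure, chosen as the smallest sizes at which
the statistical properties are stable: recovery benchmarks use 600 × 2000
matrices with 10 × 5-fold ensembles capped at 300 trees; permutation
calibration uses 20 independent 150 × 500 datasets with $B = 19$ and a
1 × 2-fold refit; the pseudo-bulk bridge trains on 120 reference samples
and predicts 12 pseudo-bulk samples of 2000 cells each. Full-scale defaults
(100 × 10, 5000 trees) remain the package defaults.

## Known limitations

* The learner is XGBoost; the package wraps, rather than reimplements,
  gradient boosting, and inherits its numerical behavior.
* The generator's independence across genes understates the correlation
  structure of real transcriptomes; marker-recovery rates on synthetic data
  are optimistic in that respect.
* L2 boosting is not robust to outlying purity labels; tumor types whose
  label quality is poor will be predicted poorly, and no outlier
  down-weighting is attempted.
* The permutation test permutes training labels only; it tests the
  expression–purity association as learned by this pipeline, not any
  particular gene's marginal association.
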