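---
title: "Nested marker selection for untargeted LC-MS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested marker selection for untargeted LC-MS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanest)
```

## The problem

Untargeted LC-MS profiling of a replicated plant collection — here the
emulated design is 18 hop (*Humulus lupulus*) cultivars, each with 3
biological and 2 technical replicates, acquired in 9 batches padded with 5
pooled-QC and 3 blank injections each — produces a peak table of a few
thousand features whose values carry, besides biology, instrumental drift
within and between batches, missing peaks, and irreproducible signals.
On top of that, class labels for cultivars are themselves uncertain
(genetic, geographic and usage classifications disagree), and with 54
analysis samples against ~3000 features, any feature selection that sees
the test data inflates the apparent classification accuracy.

`metanest` addresses the three layers in order: QC-anchored pre-treatment,
metabolome-derived class labels, and a nested resampling selection whose
held-out folds never inform which features are kept.

## Pre-treatment model and assumptions

The pipeline order is fixed — impute, drift-correct, RSD-filter, average
technical replicates, autoscale, bind polarities — and each stage's output
satisfies the next stage's preconditions.

**Imputation.** Missing peak areas in LC-MS tables are predominantly
left-censored, but their values are strongly predictable from co-varying
features (shared drift, shared biology). `impute_missing()` follows the
iterative random-forest recipe: initialize holes with feature means, then
repeatedly re-predict each incomplete feature from the others with a
bagged regression-tree ensemble, stopping at the first increase of the
normalized squared difference between successive sweeps and returning the
previous sweep. Two departures from the textbook algorithm, both for
scale: each feature is predicted from its `n_predictors = 15` most
correlated companions rather than all features, and the ensemble is small
(10 trees, depth 3). The relevant test is behavioral: on censored
synthetic tables the ensemble must strictly beat feature-mean imputation
in NRMSE against the held-out truth.

**QC drift correction.** The pooled QC — an equal mixture of all study
extracts injected throughout every batch — is a physical constant, so any
trend in its signal is instrumental. Per feature, a regressor trained on
QC rows only, with injection order and batch as covariates, yields a
prediction S_pred for every injection, and

S_corr = S_obs / S_pred × 1000.

A cell whose observation equals its prediction maps to exactly 1000, the
dimensionless target constant. The default regressor is in-package
gradient boosting with depth-one trees (50 rounds, learning rate 0.1,
minimum leaf 2): with only two covariates, of which injection order
already determines the batch, stumps are fully expressive, and
squared-error stump fitting makes the correction exactly equivariant to
rescaling a feature's column. Predictions are floored at 10⁻⁶ × the
feature's QC mean, so the division cannot blow up. Blanks take no part in
training. The hyperparameters are stated choices, exposed via
`model_params`, since the workflow this emulates does not publish its
boosting settings.

**RSD filter.** Features with QC relative standard deviation (n−1 sd /
mean × 100) above 30% are removed *before* correction takes credit; after
correction the RSD is recomputed and reported but never re-filters,
mirroring the observation that corrected tables need no second pass. A
zero-mean QC feature has no defined RSD and is removed and flagged rather
than crashing; a feature with identical QC values (RSD 0) is never
removed.

**Averaging and scaling.** Technical replicates are averaged on the
corrected (not log) scale, after which injection order and batch have no
meaning and are cleared; each feature is then centred and scaled to unit
variance, and zero-variance features are dropped with a warning. The two
polarity tables are bound by column at the very end, rows aligned by
sample id, feature ids namespaced `pos_` / `neg_`.

**Which scale feeds which statistic.** The source workflow scales "all
data tables", but a fold change on centred data is undefined. The minimal
consistent reading, adopted here: the moderated t-test and the fold change
are computed on the log2-transformed (respectively raw) corrected,
averaged, *unscaled* table; PLS, PCA and HCA operate on the autoscaled
table.

## Metabolome-based labeling

Scores on the first 10 principal components (centring and unit-variance
scaling applied internally; the count is capped at what the sample count
supports), Ward.D2 linkage on Manhattan distances between score vectors,
tree cut at k = 2. Ward's recurrence is applied verbatim to the squared
Manhattan dissimilarities with heights reported on the original scale —
the widely used "Ward.D2" convention — even though Ward's objective
presumes squared Euclidean geometry; reproducing the named linkage exactly
was preferred over geometric purity, and the implementation is verified
against both the reference implementation and a closed-form brute-force
agglomerator.

Cluster numbering is deterministic: when the unscaled table is available,
cluster 1 is the cluster with the higher grand-mean log2 intensity
(marker compounds in the emulated study are systematically more abundant
in group 1); otherwise the smaller cluster is called 1. Per-cultivar
consensus labels are the majority over the three biological replicates
(a tie is impossible with three and is an error with even counts).

## The selection statistics

**Moderated t.** Per-feature two-group least squares with empirical-Bayes
variance shrinkage: s²_post = (d₀s₀² + d s²)/(d₀ + d), the prior (d₀, s₀²)
moment-matched to the scaled-F marginal of the log sample variances via
the closed digamma/trigamma equations (trigamma inverted by Newton
iteration), t referred to d + d₀ degrees of freedom, Benjamini–Hochberg
step-up adjustment. Features with zero sample variance are excluded from
prior estimation. Two numerical conventions worth noting:

- when the log-variance dispersion does not exceed its expected trigamma
  noise, the prior df is infinite and the prior variance is set to the
  *geometric mean* of the sample variances, so that a table of exactly
  equal variances is a fixed point of the shrinkage (the bias-corrected
  alternative would inflate it by exp(log(d/2) − digamma(d/2)));
- the BH-adjusted values are *not* a fixed point of the step-up map — no
  correct implementation's are, e.g. (0.2, 0.2, 0.9) → (0.3, 0.3, 0.9) →
  (0.45, 0.45, 0.9) — so correctness is asserted by agreement with the
  reference implementation, monotonicity, and output ≥ input.

**PLS and VIP.** Single-response NIPALS with X-deflation; for a binary
class the response is coded +1/−1 and centred. VIP_j =
√(p Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a), so mean(VIP²) = 1 identically.
The component count is tuned by stratified 10-fold cross-validated Q²,
choosing the *smallest* count within 0.01 of the maximum — a parsimony
margin standard in chemometrics, without which CV routinely keeps a
second component that corrects the first's estimation error on strongly
one-component data. An optional permutation test (+1-smoothed empirical
p) measures model significance; it is off inside the nested loops for
cost.

**GLM validation.** Ridge-penalized logistic regression by
Newton/IRLS (intercept unpenalized, default λ = 10⁻³). The ridge exists
because strong marker sets make outer folds perfectly separable, where
the unpenalized MLE diverges; 10⁻³ is small enough to leave accuracy
untouched.

## The nested scheme and its reading

The outer loop is a stratified 10-fold split of the 54 samples. The
phrase "each of the remaining nine inner folds were bootstrapped five
times" admits two topologies; the default here (`inner_mode = "cv"`)
treats the nine retained folds as a 9-iteration inner cross-validation
and bootstraps each iteration's *training* portion (8 of 9 folds,
stratified within class, to original size) — a lone 5–6-sample fold could
not support a PLS fit. The literal alternative (`inner_mode = "fold"`)
bootstraps each single fold and is selectable for comparison. All
intersections — across the five bootstraps of an iteration, across the
nine iterations, and across the ten outer sets — are strict; an empty
outer set is recorded, its accuracy left `NA` with a loud warning, and
the final intersection proceeds. GLM accuracy is a diagnostic and never
vetoes a set.

## What the generator emulates, and what a green test establishes

`simulate_study()` states the world explicitly: feature baselines
lognormal (log2 mean 17, sd 2), cultivar and biological-replicate effects
lognormal (sd 0.5 and 0.25 log2 units), injection noise 0.2 log2 units,
markers shifted by a configurable log2 effect between two latent cultivar
groups (up in group 1), monotone exponential within-batch drift (default
±30% over a batch, per-feature direction and 20% jitter, resetting at
batch boundaries as column re-equilibration does) times a shared
per-batch offset (sd 0.1 log2), pooled QC composed pre-noise then subject
to the same drift and noise, blanks at 0.1% of baseline, and missingness
drawn without replacement with weight exp(−censor_strength · z) at an
exact overall rate (default 5%, censor strength 3). Same seed, same
tables, bit for bit.

Deliberately *not* emulated: correlated feature blocks (each feature's
biology is independent), adducts/isotopes of one compound, retention-time
structure in the drift, and heavy-tailed contamination. Two consequences
matter for interpreting green tests. First, with only 20 planted markers
among 1000 independent features, the group direction carries less
variance than the cultivar random effects, so the 10-PC clustering
recovers cultivar structure — biological replicates co-cluster, the
tested property — but not the two-group split; in real data the group
signal rides on many correlated compounds (e.g. the alpha-acid family).
The recovery benchmark therefore runs the selection against the planted
ground-truth groups, which is precisely what it measures: the selection
machinery, not the labeler. Second, the null (selection-bias) benchmark
randomizes labels at the *sample* level: cultivar-level null labels are
partially predictable from cultivar identity alone, because replicates of
one cultivar span outer folds — with cultivar-level null labels the
outer GLM reaches ~0.98 accuracy from pure cultivar memorization, versus
~0.47 at sample level. That leakage is a property of any replicated
design, not of the scheme; the unbiasedness claim is about labels the
data cannot identify. Under the default three-criterion cut-off, null
data yields empty intersections (the correct outcome), so the null
benchmark disables the cut-off to exercise the outer GLM on every fold.
The recovery benchmark also generates with `missing_rate = 0`: it
isolates selection, and imputation has its own NRMSE criterion.

## Numerical choices and degenerate inputs

- Missing markers are `NA` end to end, never 0; writing a table emits the
  `NA` sentinel, and empty cells read back as missing.
- `inject_missing()` never removes a feature's largest observed cell, so
  no feature becomes fully missing; a fully missing feature is a named
  error in the imputer.
- Prediction flooring in the drift correction: 10⁻⁶ × QC mean.
- NIPALS stops a component when ‖X'y‖ or the score norm falls below
  10⁻¹²; rank exhaustion returns fewer components with a warning.
- Dendrogram ties (duplicate points) merge at height zero first;
  `cut_dendrogram()` labels clusters 1..k in leaf order.
- IRLS convergence: relative penalized-deviance change below 10⁻¹⁰,
  error with the last deviance after 100 iterations.
- 1-based injection order and batches; injection order is global and
  unique, cleared (all-`NA`) once technical replicates are averaged.

## Limitations

Peak picking, chromatogram alignment and raw-file handling are out of
scope — the package starts from delimited peak tables. Compound
identification (adduct/isotope curation, MS², library search, molecular
networking) is likewise out of scope; retention-time grouping
(single-linkage chaining at 0.1 min) is the only automated surrogate for
grouping ions of one compound. The moderated test and fold change are
two-group only, and the GLM is binary; multi-class designs would need a
different selection core. The interface is R functions and this
document; the pipeline chains with `run_pipeline()` rather than a shell
CLI.
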