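# metanest

Marker discovery for untargeted LC-MS plant metabolomics, built around the
workflow used to classify *Humulus lupulus* (hop) brewing cultivars from
their metabolite profiles: pooled-QC based pre-treatment of peak tables,
semi-supervised labeling of samples by hierarchical clustering, and a
nested bootstrap / cross-validation feature-selection scheme that keeps
held-out data out of the selection, so the reported classification
accuracy carries no selection bias.

The package is aimed at analysts working with peak tables (samples ×
chromatographic features) from two-polarity LC-MS profiling of replicated
designs — cultivars or strains with biological and technical replicates
acquired in batches with pooled-QC and blank injections.

## What it computes

**Pre-treatment** (`run_pretreatment()`), in fixed order per polarity:

1. *Imputation* — iterative random-forest style completion of missing peak
   areas (`impute_missing()`), with the classic stopping rule on the
   normalized difference between successive imputations.
2. *QC drift correction* (`qc_drift_correct()`) — per feature, a
   gradient-boosted tree model trained on the pooled-QC injections
   (covariates: injection order, batch) predicts the expected signal
   S_pred at every injection, and each area is rescaled as

   S_corr = S_obs / S_pred × 1000

3. *Reproducibility filter* (`rsd_filter()`) — features whose relative
   standard deviation over QC injections exceeds 30% (sd/mean × 100) are
   removed; the post-correction RSD is re-checked and reported only.
4. *Technical-replicate averaging* and *autoscaling*
   (`average_technical()`, `autoscale()`), then the two polarities are
   bound by column (`bind_polarities()`) with `pos_`/`neg_` namespacing.

**Labeling** (`assign_metabolome_labels()`) — scores on the first 10
principal components, Ward.D2 hierarchical clustering on Manhattan
distances, cut at k = 2: the metabolome-based class labels.

**Nested selection** (`run_nested_selection()`) — a stratified 10-fold
outer split; within each outer training set, a 9-iteration inner
cross-validation whose training portions are bootstrapped 5 times; on
every bootstrap a *rational cut-off* keeps features passing all three of

- BH-adjusted moderated-t p < 0.05 (empirical-Bayes variance shrinkage:
  s²_post = (d₀s₀² + d s²)/(d₀ + d), moment-matched prior),
- |log₂ fold change| > 1,
- VIP > 1 from a component-tuned NIPALS PLS
  (VIP_j = √(p · Σ_a SSY_a w²_ja / Σ_a SSY_a)).

Bootstrap sets are intersected within each inner iteration, across the
nine iterations (giving the outer set S_o), and finally across the ten
outer sets. Each S_o is validated by a ridge logistic GLM on its held-out
outer fold. `build_marker_table()` reports the final set with m/z,
retention time, polarity, full-data VIP and log₂ fold change, and
retention-time groups.

A first-class synthetic study generator (`simulate_study()`) emulates the
full design — 18 cultivars × 3 biological × 2 technical replicates in 9
batches with 5 QC + 3 blank injections each, smooth within-batch drift,
batch offsets, pooled-QC composition, planted markers, censored
missingness — with ground truth, so every stage is testable offline.

## Worked example

```r
library(metanest)

cfg <- simulation_config(n_features_pos = 150, n_features_neg = 150,
                         n_markers = 10, marker_log2_effect = 2, seed = 2025)
sim <- simulate_study(cfg)
sim$pos
#> <peak_table> 180 injections x 150 features (raw scale)
#>   roles: 108 study, 45 qc, 27 blank
#>   polarity: 150 positive, 0 negative
#>   missing cells: 1350 (5.0%)

pre <- run_pretreatment(sim$pos, sim$neg, impute_args = list(seed = 2025))
pre$scaled
#> <peak_table> 54 injections x 300 features (autoscaled)
#>   roles: 54 study, 0 qc, 0 blank
#>   polarity: 150 positive, 150 negative

labels <- assign_metabolome_labels(pre$scaled, raw_table = pre$raw)
labels
#> <cluster_assignment> 54 samples in 2 clusters on 10 PCs
#> cluster
#>  1  2
#> 30 24

sel <- run_nested_selection(pre$scaled, pre$raw,
                            sim$truth$group_of_cultivar[pre$scaled$samples$cultivar],
                            seed = 2025)
sel
#> <selection_result> 10 outer folds; final set: 10 feature(s)
#>   outer set sizes: 10, 10, 10, 10, 10, 10, 10, 10, 10, 10
#>   outer accuracies: 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00

mk <- build_marker_table(sel, pre$raw, pre$scaled,
                         sim$truth$group_of_cultivar[pre$scaled$samples$cultivar])
mk
#> # A tibble: 10 x 7
#>   feature_id polarity    mz    rt   vip log2_fc rt_group
#> 1 pos_P0002  positive  417. 28.0   3.12    2.09       10
#> 2 pos_P0004  positive  151. 12.2   3.40    2.03        3
#> ...
sum(mk$feature_id %in% sim$truth$marker_ids)
#> [1] 10
```

All ten planted markers are recovered, with no false features; the 54
analysis samples (18 × 3 after technical averaging) separate perfectly on
every outer fold. The 180 injections per polarity are 108 study + 45 QC +
27 blank, as the emulated design prescribes. `tidy()`, `glance()` and
`autoplot()` methods are available for the fitted objects (moderated
tests, PLS models, GLMs, cluster assignments, selection results, PCA and
dendrograms).

The packaged cultivar annotation table (`hop_cultivars()`) carries the
18 cultivars' growing region, germplasm origin, usage type and two-group
metabolome label used in the study this package emulates.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch — it
simulates a two-polarity study in the emulated design (1000 features, 20
planted markers), pre-treats it, assigns metabolome labels, runs the
nested selection against the planted groups and builds the marker report —
and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and summary statistics are logged to stderr.

## Documentation

The methods vignette (`vignettes/nested-marker-selection.Rmd`) describes
the model assumptions, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the numerical design
choices.
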