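Package: metanest
Title: Nested Marker Selection for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-treatment and semi-supervised marker discovery for
    untargeted LC-MS peak tables. Implements pooled-QC based signal drift
    correction with gradient-boosted trees, random-forest style iterative
    imputation of missing peak areas, QC reproducibility (RSD) filtering,
    technical-replicate averaging and autoscaling; metabolome-based sample
    labeling by hierarchical clustering of principal-component scores
    (Ward.D2 linkage, Manhattan distance); and a nested bootstrap /
    cross-validation feature-selection scheme combining a moderated
    t-statistic with Benjamini-Hochberg adjustment, fold change and
    PLS variable importance in projection (VIP) into a rational cut-off,
    validated fold-wise with a ridge-penalized logistic model. A synthetic
    study generator with ground truth makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
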