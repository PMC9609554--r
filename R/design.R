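#' Describe the replication / batch structure of a profiling experiment
#'
#' A `study_design` records how many cultivars, biological replicates,
#' technical replicates and batches an LC-MS run comprises, and how many
#' pooled-QC and blank injections pad each batch. The default values
#' reproduce the hop-cultivar study layout this package emulates: 18
#' cultivars x 3 biological x 2 technical replicates distributed over 9
#' batches, each batch holding 6 study samples injected twice plus 5 QC and
#' 3 blank injections.
#'
#' @param n_cultivars,n_bio,n_tech Positive integers: cultivars, biological
#'   replicates per cultivar, technical replicates (repeat injections) per
#'   biological replicate.
#' @param n_batches Number of acquisition batches; study samples must be
#'   evenly distributable (`n_cultivars * n_bio` divisible by `n_batches`).
#' @param qc_per_batch,blank_per_batch Pooled-QC and blank injections per
#'   batch.
#' @param cultivar_annotations Optional tibble mapping `cultivar` to
#'   `region`, `genetic_origin` and `usage_type` (see [hop_cultivars()]).
#' @return A `study_design` list.
#' @export
study_design <- function(n_cultivars = 18, n_bio = 3, n_tech = 2,
                         n_batches = 9, qc_per_batch = 5, blank_per_batch = 3,
                         cultivar_annotations = NULL) {
  stopifnot(n_cultivars >= 1, n_bio >= 1, n_tech >= 1, n_batches >= 1,
            qc_per_batch >= 0, blank_per_batch >= 0)
  n_samples <- n_cultivars * n_bio
  if (n_samples %% n_batches != 0)
    stop(n_cultivars, " x ", n_bio, " study samples are not distributable over ",
         n_batches, " batches")
  structure(
    list(n_cultivars = n_cultivars, n_bio = n_bio, n_tech = n_tech,
         n_batches = n_batches, qc_per_batch = qc_per_batch,
         blank_per_batch = blank_per_batch,
         cultivar_annotations = cultivar_annotations),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d cultivars x %d bio x %d tech = %d study injections\n",
    x$n_cultivars, x$n_bio, x$n_tech, x$n_cultivars * x$n_bio * x$n_tech))
  cat(sprintf("  %d batches; per batch: %d qc, %d blank\n",
              x$n_batches, x$qc_per_batch, x$blank_per_batch))
  invisible(x)
}

#' Hop cultivar annotation table
#'
#' Returns the packaged annotation table for the 18 brewing cultivars of
#' *Humulus lupulus* whose profiling study this package emulates: growing
#' region (Central Europe / North America / Oceania, six cultivars each),
#' germplasm assignment from published EST-SSR genotyping (6 European / 12
#' North American), usage type (10 aroma / 8 dual use), and the two-group
#' metabolome-based label the original analysis assigned. The region column
#' is a reconstruction from the cultivars' documented breeding origins; the
#' remaining columns are a transcription of the published study metadata.
#'
#' @return A tibble with columns `cultivar`, `region`, `genetic_origin`,
#'   `usage_type`, `new_label`.
#' @export
hop_cultivars <- function() {
  path <- system.file("extdata", "cultivar_annotations.csv",
                      package = "metanest", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    cultivar = readr::col_character(),
    region = readr::col_character(),
    genetic_origin = readr::col_character(),
    usage_type = readr::col_character(),
    new_label = readr::col_integer()
  ), progress = FALSE)
}
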