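#' Group selected features by retention time
#'
#' Single-linkage chaining on |rt difference|: two signals join the same
#' group whenever a chain of pairwise gaps of at most `tolerance_min`
#' connects them. Polarity is ignored — the positive and negative ions of
#' one compound co-elute and should co-group. Groups are numbered 1..G in
#' order of increasing retention time.
#'
#' @param features Tibble of feature metadata (`feature_id`, `rt`).
#' @param tolerance_min Chain threshold in minutes (default 0.1).
#' @return Named integer vector mapping feature_id to group id.
#' @export
group_features_by_rt <- function(features, tolerance_min = 0.1) {
  stopifnot(tolerance_min > 0)
  if (nrow(features) == 0) return(stats::setNames(integer(0), character(0)))
  o <- order(features$rt)
  rt <- features$rt[o]
  new_group <- c(TRUE, diff(rt) > tolerance_min)
  grp <- cumsum(new_group)
  out <- integer(nrow(features))
  out[o] <- grp
  stats::setNames(out, features$feature_id)
}

#' Build the marker report table
#'
#' One row per finally selected feature with its m/z, retention time,
#' polarity, VIP and log2 fold change recomputed on the full dataset (a
#' single component-tuned PLS on the full autoscaled table; fold change on
#' the full corrected table), plus a retention-time group id. An empty
#' selection gives a header-only (zero-row) table.
#'
#' @param selection A [run_nested_selection()] result.
#' @param table_raw Corrected unscaled [peak_table] (full dataset).
#' @param table_scaled Autoscaled [peak_table] (full dataset).
#' @param labels Two-group labels, one per sample.
#' @param rt_tolerance_min Retention-time grouping window, minutes.
#' @param max_components,tune_folds PLS settings for the full-data fit.
#' @return A `marker_table` tibble: `feature_id`, `polarity`, `mz`, `rt`,
#'   `vip`, `log2_fc`, `rt_group`.
#' @export
build_marker_table <- function(selection, table_raw, table_scaled, labels,
                               rt_tolerance_min = 0.1,
                               max_components = 5, tune_folds = 10) {
  ids <- if (inherits(selection, "selection_result")) selection$final_set else as.character(selection)
  if (inherits(labels, "cluster_assignment")) labels <- labels$samples$label
  empty <- tibble::tibble(feature_id = character(0), polarity = character(0),
                          mz = numeric(0), rt = numeric(0), vip = numeric(0),
                          log2_fc = numeric(0), rt_group = integer(0))
  if (length(ids) == 0) return(structure(empty, class = c("marker_table", class(empty))))
  xs <- table_scaled$intensities
  xr <- table_raw$intensities
  tuned <- tune_pls_components(xs, labels, max_components = max_components,
                               n_folds = min(tune_folds, nrow(xs)))
  fit <- suppressWarnings(fit_pls(xs, labels, tuned$n_components))
  vip <- vip_scores(fit)[ids]
  lfc <- log_fold_change(xr, labels)[ids]
  feats <- table_scaled$features[match(ids, table_scaled$features$feature_id), ]
  groups <- group_features_by_rt(feats, tolerance_min = rt_tolerance_min)
  out <- tibble::tibble(feature_id = ids, polarity = feats$polarity,
                        mz = feats$mz, rt = feats$rt,
                        vip = unname(vip), log2_fc = unname(lfc),
                        rt_group = unname(groups[ids]))
  structure(out, class = c("marker_table", class(out)))
}

#' Run the complete analysis on a two-polarity study
#'
#' Chains every stage with its defaults: pre-treatment
#' ([run_pretreatment()]), metabolome-based labeling
#' ([assign_metabolome_labels()]), nested feature selection
#' ([run_nested_selection()]) and the marker report
#' ([build_marker_table()]).
#'
#' @param pos,neg Raw [peak_table]s for the two polarities.
#' @param seed Integer seed for the stochastic stages.
#' @param rsd_threshold_pct QC RSD filter threshold.
#' @param criteria A [cutoff_criteria()].
#' @param n_pcs,k Labeling settings.
#' @param ... Further arguments passed to [run_nested_selection()].
#' @return A list: `pretreated`, `labels`, `selection`, `markers`.
#' @export
run_pipeline <- function(pos, neg, seed = 1, rsd_threshold_pct = 30,
                         criteria = cutoff_criteria(), n_pcs = 10, k = 2, ...) {
  pre <- run_pretreatment(pos, neg, rsd_threshold_pct = rsd_threshold_pct,
                          impute_args = list(seed = seed))
  labels <- assign_metabolome_labels(pre$scaled, n_pcs = n_pcs, k = k,
                                     raw_table = pre$raw)
  selection <- run_nested_selection(pre$scaled, pre$raw, labels,
                                    criteria = criteria, seed = seed, ...)
  markers <- build_marker_table(selection, pre$raw, pre$scaled, labels)
  list(pretreated = pre, labels = labels, selection = selection,
       markers = markers)
}
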