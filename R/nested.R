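#' Three-criterion rational cut-off settings
#'
#' A feature is selected only if it simultaneously (i) reaches
#' Benjamini-Hochberg adjusted moderated-t significance below
#' `alpha_adjusted`, (ii) exceeds the fold-change threshold, and (iii) has
#' PLS VIP above `vip_threshold`. The fold-change criterion is interpreted
#' on the log2 scale by default (`fc_mode = "abs_log2"`, threshold on
#' `|log2 FC|`); `"signed_log2"` and `"raw_ratio"` are selectable.
#'
#' A criterion can be disabled (the null benchmark uses this):
#' `alpha_adjusted >= 1`, `fc_threshold = -Inf`, or `vip_threshold < 0`
#' pass every feature, and the corresponding computation is skipped.
#'
#' @param alpha_adjusted Adjusted-p threshold (default 0.05).
#' @param fc_threshold Fold-change threshold, log2 units for the log2
#'   modes (default 1.0).
#' @param vip_threshold VIP threshold (default 1.0).
#' @param fc_mode `"abs_log2"`, `"signed_log2"` or `"raw_ratio"`.
#' @return A `cutoff_criteria` list.
#' @export
cutoff_criteria <- function(alpha_adjusted = 0.05, fc_threshold = 1.0,
                            vip_threshold = 1.0,
                            fc_mode = c("abs_log2", "signed_log2", "raw_ratio")) {
  fc_mode <- match.arg(fc_mode)
  stopifnot(alpha_adjusted > 0)
  structure(list(alpha_adjusted = alpha_adjusted, fc_threshold = fc_threshold,
                 vip_threshold = vip_threshold, fc_mode = fc_mode),
            class = "cutoff_criteria")
}

#' Apply the rational cut-off to one (resampled) training set
#'
#' Runs the three criteria on the same samples — moderated t-test on the
#' log2-transformed corrected intensities, fold change on the corrected
#' (raw-scale) intensities, VIP from a component-tuned PLS fit on the
#' autoscaled intensities — and returns the features passing all three.
#'
#' @param train_scaled Autoscaled matrix (samples x features).
#' @param train_raw Positive corrected-intensity matrix, same features.
#' @param labels Two-group labels, one per row.
#' @param criteria A [cutoff_criteria()].
#' @param max_components,tune_folds PLS tuning settings.
#' @return Character vector of selected feature ids (column names).
#' @export
rational_cutoff <- function(train_scaled, train_raw, labels,
                            criteria = cutoff_criteria(),
                            max_components = 5, tune_folds = 10) {
  train_scaled <- as.matrix(train_scaled)
  train_raw <- as.matrix(train_raw)
  if (!identical(colnames(train_scaled), colnames(train_raw)))
    stop("scaled and raw matrices must share features (column names)")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("both classes must be present")
  feats <- colnames(train_scaled)
  pass <- rep(TRUE, length(feats))
  if (criteria$alpha_adjusted < 1) {
    mt <- moderated_t_test(log2(train_raw), labels)
    pass <- pass & (mt$table$p_adjusted < criteria$alpha_adjusted)
  }
  if (is.finite(criteria$fc_threshold)) {
    lfc <- log_fold_change(train_raw, labels)
    pass <- pass & switch(criteria$fc_mode,
      abs_log2 = abs(lfc) > criteria$fc_threshold,
      signed_log2 = lfc > criteria$fc_threshold,
      raw_ratio = 2^lfc > criteria$fc_threshold)
  }
  if (criteria$vip_threshold >= 0) {
    tuned <- tune_pls_components(train_scaled, labels,
                                 max_components = max_components,
                                 n_folds = min(tune_folds, nrow(train_scaled)))
    fit <- suppressWarnings(fit_pls(train_scaled, labels, tuned$n_components))
    pass <- pass & (vip_scores(fit) > criteria$vip_threshold)
  }
  feats[pass]
}

#' Stratified bootstrap resample
#'
#' Samples with replacement to the original size, independently within
#' each class, so both classes are always present in the draw.
#'
#' @param idx Integer vector of sample indices.
#' @param labels Class label per element of `idx`.
#' @param seed Optional integer seed; by default the current RNG stream is
#'   used (the nested scheme seeds once globally).
#' @return Integer multiset of the same length as `idx`.
#' @export
bootstrap_resample <- function(idx, labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("both classes must be present")
  out <- integer(0)
  for (lv in levels(droplevels(labels))) {
    pool <- idx[labels == lv]
    out <- c(out, sample(pool, length(pool), replace = TRUE))
  }
  out
}

#' Held-out accuracy of a GLM restricted to a feature set
#'
#' @param train,test Matrices restricted to the selected features.
#' @param train_labels,test_labels Class labels.
#' @param ridge Ridge penalty of the logistic fit.
#' @return Accuracy in `[0, 1]`.
#' @export
glm_validate <- function(train, train_labels, test, test_labels, ridge = 1e-3) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (ncol(train) == 0) stop("empty feature set")
  fit <- fit_logistic_glm(train, train_labels, ridge = ridge)
  glm_accuracy(fit, test, test_labels)
}

#' Nested bootstrap / cross-validation feature selection
#'
#' The selection scheme this package exists for. An outer stratified
#' `n_outer`-fold split provides held-out validation sets; for each outer
#' split, the remaining folds define an inner cross-validation whose
#' training portions are bootstrapped `n_boot` times, the rational cut-off
#' runs on every bootstrap, and strict set intersections are taken — first
#' across the bootstraps of an inner iteration, then across the inner
#' iterations — giving the outer feature set `S_o`. A ridge-logistic GLM
#' restricted to `S_o` is trained on the outer-training samples and scored
#' on the held-out fold. The final marker set is the intersection of all
#' outer sets. An empty `S_o` is recorded as such, its accuracy is `NA`
#' (flagged loudly), and the final intersection proceeds (empty result).
#'
#' `inner_mode = "cv"` (default) reads "each inner fold bootstrapped" as
#' bootstrap-the-inner-training-set (the other folds); the literal
#' alternative `"fold"` bootstraps each single inner fold on its own.
#'
#' @param table_scaled Autoscaled [peak_table] or matrix (samples x
#'   features).
#' @param table_raw Corrected unscaled counterpart, same samples/features.
#' @param labels Two-group labels, one per sample (a vector or a
#'   `cluster_assignment`).
#' @param criteria A [cutoff_criteria()].
#' @param n_outer Outer folds (default 10).
#' @param n_boot Bootstraps per inner iteration (default 5).
#' @param seed Integer seed governing folds and bootstraps.
#' @param max_components,tune_folds PLS settings per bootstrap fit.
#' @param inner_mode `"cv"` or `"fold"` (see above).
#' @param ridge GLM ridge penalty.
#' @return A `selection_result`: `outer_sets`, `outer_accuracies`,
#'   `final_set`, `folds`, and a per-fold `diagnostics` tibble.
#' @export
run_nested_selection <- function(table_scaled, table_raw, labels,
                                 criteria = cutoff_criteria(),
                                 n_outer = 10, n_boot = 5, seed = 1,
                                 max_components = 5, tune_folds = 10,
                                 inner_mode = c("cv", "fold"),
                                 ridge = 1e-3) {
  inner_mode <- match.arg(inner_mode)
  xs <- if (inherits(table_scaled, "peak_table")) table_scaled$intensities else as.matrix(table_scaled)
  xr <- if (inherits(table_raw, "peak_table")) table_raw$intensities else as.matrix(table_raw)
  if (inherits(labels, "cluster_assignment")) labels <- labels$samples$label
  labels <- as.factor(labels)
  n <- nrow(xs)
  stopifnot(length(labels) == n, nrow(xr) == n, n >= n_outer)
  set.seed(seed)
  folds <- stratified_folds(labels, n_outer)
  outer_sets <- vector("list", n_outer)
  acc <- rep(NA_real_, n_outer)
  diag_rows <- vector("list", n_outer)
  for (o in seq_len(n_outer)) {
    test_idx <- which(folds == o)
    train_folds <- setdiff(seq_len(n_outer), o)
    inner_sets <- vector("list", length(train_folds))
    inner_sizes <- integer(length(train_folds))
    for (ii in seq_along(train_folds)) {
      i <- train_folds[ii]
      inner_idx <- if (inner_mode == "cv") {
        which(folds != o & folds != i)
      } else {
        which(folds == i)
      }
      boot_sets <- vector("list", n_boot)
      for (b in seq_len(n_boot)) {
        bs <- bootstrap_resample(inner_idx, labels[inner_idx])
        boot_sets[[b]] <- rational_cutoff(
          xs[bs, , drop = FALSE], xr[bs, , drop = FALSE], labels[bs],
          criteria, max_components = max_components, tune_folds = tune_folds)
      }
      inner_sets[[ii]] <- Reduce(intersect, boot_sets)
      inner_sizes[ii] <- length(inner_sets[[ii]])
    }
    s_o <- Reduce(intersect, inner_sets)
    outer_sets[[o]] <- s_o
    if (length(s_o) > 0) {
      train_idx <- which(folds != o)
      acc[o] <- glm_validate(xs[train_idx, s_o, drop = FALSE],
                             labels[train_idx],
                             xs[test_idx, s_o, drop = FALSE],
                             labels[test_idx], ridge = ridge)
    } else {
      warning("outer fold ", o, ": empty selected set; accuracy undefined")
    }
    diag_rows[[o]] <- tibble::tibble(
      outer_fold = o, n_test = length(test_idx),
      set_size = length(s_o), accuracy = acc[o],
      inner_set_sizes = list(inner_sizes))
  }
  final_set <- Reduce(intersect, outer_sets)
  if (length(final_set) == 0)
    warning("final intersected marker set is empty")
  structure(list(outer_sets = outer_sets, outer_accuracies = acc,
                 final_set = final_set, folds = folds,
                 diagnostics = dplyr::bind_rows(diag_rows),
                 criteria = criteria, seed = seed, inner_mode = inner_mode),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d outer folds; final set: %d feature(s)\n",
              length(x$outer_sets), length(x$final_set)))
  cat(sprintf("  outer set sizes: %s\n",
              paste(lengths(x$outer_sets), collapse = ", ")))
  cat(sprintf("  outer accuracies: %s\n",
              paste(ifelse(is.na(x$outer_accuracies), "NA",
                           sprintf("%.2f", x$outer_accuracies)), collapse = ", ")))
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$diagnostics

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_final = length(x$final_set),
                 mean_accuracy = mean(x$outer_accuracies, na.rm = TRUE),
                 n_empty_folds = sum(lengths(x$outer_sets) == 0),
                 seed = x$seed)
}
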