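#' Impute missing peak areas by iterative tree-ensemble regression
#'
#' Random-forest style missing-value imputation: missing cells are
#' initialized with feature means, then features are revisited (in order of
#' increasing missingness) and each feature's holes are re-predicted from
#' the other features with a bagged regression-tree ensemble, iterating
#' until the normalized squared difference between successive imputations
#' first increases (the classic stopping rule) or `max_iter` is reached.
#' The imputation in force before the increase is returned. Observed cells
#' are never touched.
#'
#' For speed each feature is predicted from its `n_predictors` most
#' correlated companions (correlation on the current completed matrix)
#' rather than from all ~3000 features; peak tables are strongly collinear
#' (shared drift, shared biology) so a small predictor set carries most of
#' the signal.
#'
#' @param table An unscaled [peak_table].
#' @param max_iter Maximum sweeps over all incomplete features.
#' @param seed Integer seed (tree bootstraps are random).
#' @param regressor `"forest"` (default) or `"mean"` (single-pass feature
#'   means, the baseline the ensemble must beat).
#' @param n_trees,max_depth,n_predictors Ensemble size, tree depth and
#'   companion-feature count for the forest regressor.
#' @return The completed [peak_table]; no `NA` cells remain.
#' @export
impute_missing <- function(table, max_iter = 10L, seed = 1L,
                           regressor = c("forest", "mean"),
                           n_trees = 10L, max_depth = 3L, n_predictors = 15L) {
  validate_peak_table(table)
  regressor <- match.arg(regressor)
  if (table$scaled) stop("impute_missing requires an unscaled table")
  m <- table$intensities
  fully_missing <- colSums(!is.na(m)) == 0
  if (any(fully_missing))
    stop("feature(s) with no observed values: ",
         paste(table$features$feature_id[fully_missing], collapse = ", "))
  if (!anyNA(m)) return(table)
  set.seed(seed)
  miss <- is.na(m)
  mu <- colMeans(m, na.rm = TRUE)
  cur <- m
  for (j in which(colSums(miss) > 0)) cur[miss[, j], j] <- mu[j]
  if (regressor == "mean") {
    out <- table; out$intensities <- cur
    return(out)
  }
  targets <- which(colSums(miss) > 0)
  targets <- targets[order(colSums(miss)[targets])]
  prev <- cur
  prev_delta <- Inf
  for (iter in seq_len(max_iter)) {
    before <- cur
    cc <- suppressWarnings(stats::cor(cur))
    for (j in targets) {
      obs_rows <- which(!miss[, j])
      mis_rows <- which(miss[, j])
      comp <- setdiff(order(-abs(cc[, j])), j)
      comp <- comp[!is.na(cc[comp, j])]
      comp <- utils::head(comp, n_predictors)
      if (length(comp) == 0) next
      fit <- bagged_trees_fit(cur[obs_rows, comp, drop = FALSE], cur[obs_rows, j],
                              n_trees = n_trees, max_depth = max_depth)
      cur[mis_rows, j] <- predict(fit, cur[mis_rows, comp, drop = FALSE])
    }
    delta <- sum((cur[miss] - before[miss])^2) / max(sum(cur[miss]^2), .Machine$double.eps)
    if (delta >= prev_delta) {
      cur <- before   # first increase: keep the previous sweep's imputation
      break
    }
    prev_delta <- delta
  }
  out <- table
  out$intensities <- cur
  out
}

#' QC-based signal drift correction
#'
#' Removes injection-order drift and batch offsets using the pooled-QC
#' injections: per feature, a regressor (default: gradient-boosted stumps)
#' is trained on the QC rows only, with injection order and batch as
#' covariates, and used to predict the expected QC-level signal
#' `S_predicted` at every injection. Each peak area is then rescaled as
#'
#'   `S_corrected = S_observed / S_predicted * 1000`
#'
#' so a cell whose observed area equals the model prediction maps exactly
#' to the target constant 1000. Predictions are floored at
#' `1e-6 * mean(QC)` per feature so the division can never blow up. Blank
#' rows take no part in training (only QC rows do) but are corrected like
#' every other row.
#'
#' @param table A [peak_table] with no missing values and at least 3 QC rows.
#' @param model_params List of regressor settings: `n_rounds`,
#'   `learning_rate`, `min_obs` for the boosted stumps.
#' @param regressor `"gbt"` (gradient-boosted stumps, default) or `"mean"`
#'   (constant QC mean — turns the correction into simple QC-mean scaling).
#' @param target_constant Scale constant of the correction equation.
#' @param rsd_threshold_pct Threshold used in the report's pass-rate summary.
#' @return A list: `table` (corrected [peak_table]), `model`
#'   (`correction_model`), `report` (tibble: `feature_id`, `rsd_before`,
#'   `rsd_after` in %, plus pass-rate attributes).
#' @export
qc_drift_correct <- function(table,
                             model_params = list(n_rounds = 50L,
                                                 learning_rate = 0.1,
                                                 min_obs = 2L),
                             regressor = c("gbt", "mean"),
                             target_constant = 1000,
                             rsd_threshold_pct = 30) {
  validate_peak_table(table)
  regressor <- match.arg(regressor)
  if (anyNA(table$intensities))
    stop("qc_drift_correct requires a complete table; impute first")
  qc_rows <- which(table$samples$role == "qc")
  if (length(qc_rows) < 3) stop("need >= 3 QC rows, got ", length(qc_rows))
  covars <- cbind(injection_order = as.numeric(table$samples$injection_order),
                  batch = as.numeric(table$samples$batch))
  m <- table$intensities
  corrected <- m
  models <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    yq <- m[qc_rows, j]
    fit <- if (regressor == "gbt") {
      gbt_fit(covars[qc_rows, , drop = FALSE], yq,
              n_rounds = model_params$n_rounds,
              learning_rate = model_params$learning_rate,
              min_obs = model_params$min_obs)
    } else {
      structure(list(init = mean(yq), learning_rate = 0, var = integer(0),
                     split = numeric(0), left = numeric(0),
                     right = numeric(0)), class = "gbt")
    }
    pred <- predict(fit, covars)
    pred <- pmax(pred, 1e-6 * mean(yq))
    corrected[, j] <- m[, j] / pred * target_constant
    models[[j]] <- fit
  }
  out <- table
  out$intensities <- corrected
  rsd_before <- feature_rsd(m[qc_rows, , drop = FALSE])
  rsd_after <- feature_rsd(corrected[qc_rows, , drop = FALSE])
  report <- tibble::tibble(feature_id = table$features$feature_id,
                           rsd_before = rsd_before, rsd_after = rsd_after)
  attr(report, "pass_rate_before") <-
    mean(rsd_before < rsd_threshold_pct, na.rm = TRUE)
  attr(report, "pass_rate_after") <-
    mean(rsd_after < rsd_threshold_pct, na.rm = TRUE)
  model <- structure(list(models = models,
                          feature_id = table$features$feature_id,
                          target_constant = target_constant),
                     class = "correction_model")
  list(table = out, model = model, report = report)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %d per-feature boosted-stump models, target %g\n",
              length(x$models), x$target_constant))
  invisible(x)
}

# per-feature RSD (%) over the rows of a matrix, n-1 standard deviation
feature_rsd <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  unname(ifelse(mu == 0, NA_real_, sdv / mu * 100))
}

#' Filter features by QC reproducibility (RSD)
#'
#' Per feature, the relative standard deviation over the pooled-QC rows is
#' `sd / mean * 100` (n-1 standard deviation); features exceeding the
#' threshold are removed. A feature whose QC mean is zero has no defined
#' RSD and is removed and flagged rather than crashing. Features whose QC
#' values are all equal (RSD 0) are always retained.
#'
#' @param table A [peak_table] containing QC rows.
#' @param threshold_pct Maximum tolerated QC RSD, percent.
#' @return A list: `table` (filtered [peak_table]) and `report` (tibble:
#'   `feature_id`, `rsd`, `retained`).
#' @export
rsd_filter <- function(table, threshold_pct = 30) {
  validate_peak_table(table)
  stopifnot(threshold_pct > 0)
  qc_rows <- which(table$samples$role == "qc")
  if (length(qc_rows) == 0) stop("no QC rows present")
  rsd <- feature_rsd(table$intensities[qc_rows, , drop = FALSE])
  retained <- !is.na(rsd) & rsd <= threshold_pct
  report <- tibble::tibble(feature_id = table$features$feature_id,
                           rsd = rsd, retained = retained)
  out <- pt_select_features(table, table$features$feature_id[retained])
  list(table = out, report = report)
}

#' Average technical replicates
#'
#' Collapses repeat injections of each biological sample to their
#' arithmetic mean (on the corrected intensity scale), yielding one row per
#' (cultivar, biological replicate). QC and blank rows are dropped — they
#' have done their job by this stage — and injection order and batch no
#' longer apply, so they are cleared.
#'
#' @param table A [peak_table] whose study rows carry cultivar/bio_rep.
#' @return A [peak_table] with one study row per biological sample.
#' @export
average_technical <- function(table) {
  validate_peak_table(table)
  study <- pt_filter_samples(table, "study")
  key <- paste(study$samples$cultivar, study$samples$bio_rep, sep = "\r")
  groups <- split(seq_len(nrow(study$intensities)), key)
  first_idx <- vapply(groups, `[`, integer(1), 1)
  ord <- order(first_idx)   # keep first-appearance order
  groups <- groups[ord]
  m <- do.call(rbind, lapply(groups, function(rows) {
    colMeans(study$intensities[rows, , drop = FALSE])
  }))
  meta <- study$samples[vapply(groups, `[`, integer(1), 1), ]
  samples <- tibble::tibble(
    sample_id = sprintf("S_%s_b%d", sanitize_id(meta$cultivar), meta$bio_rep),
    role = "study", cultivar = meta$cultivar, bio_rep = meta$bio_rep,
    tech_rep = NA_integer_, batch = NA_integer_,
    injection_order = NA_integer_)
  extra <- setdiff(names(meta), sample_meta_cols)
  for (col in extra) samples[[col]] <- meta[[col]]
  peak_table(m, samples, study$features, scaled = table$scaled)
}

#' Centre and scale a peak table (autoscaling)
#'
#' Each feature is centred to mean zero and scaled to unit (n-1) standard
#' deviation. Zero-variance features carry no information and are dropped
#' with a warning. The `scaled` flag is set, releasing the non-negativity
#' invariant; the centres and scales are stored so [unscale()] can invert
#' the transform.
#'
#' @param table A complete (no `NA`) [peak_table].
#' @return The autoscaled [peak_table], with a `scaling` tibble attached.
#' @export
autoscale <- function(table) {
  validate_peak_table(table)
  if (anyNA(table$intensities)) stop("autoscale requires a complete table")
  m <- table$intensities
  sds <- apply(m, 2, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s): ",
            paste(utils::head(table$features$feature_id[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    table <- pt_select_features(table, table$features$feature_id[!drop])
    m <- table$intensities
    sds <- sds[!drop]
  }
  mus <- colMeans(m)
  out <- table
  out$intensities <- scale(m, center = mus, scale = sds)
  attr(out$intensities, "scaled:center") <- NULL
  attr(out$intensities, "scaled:scale") <- NULL
  out$scaled <- TRUE
  out$scaling <- tibble::tibble(feature_id = table$features$feature_id,
                                center = mus, scale = sds)
  out
}

#' @rdname autoscale
#' @export
unscale <- function(table) {
  if (!table$scaled || is.null(table$scaling)) stop("table is not autoscaled")
  out <- table
  out$intensities <- sweep(sweep(table$intensities, 2, table$scaling$scale, `*`),
                           2, table$scaling$center, `+`)
  out$scaled <- FALSE
  out$scaling <- NULL
  validate_peak_table(out)
  out
}

#' Run the full pre-treatment chain on a two-polarity study
#'
#' Applies the fixed stage order — impute, QC drift correction, QC-RSD
#' filter, technical-replicate averaging, autoscaling — to each polarity
#' table, then binds the polarities by column. Two bound tables are
#' returned: the analysis-ready autoscaled matrix (for PCA/HCA/PLS) and its
#' unscaled counterpart on the corrected intensity scale (for fold changes
#' and the log-intensity t-statistic). The post-correction QC RSD is
#' re-checked and reported but never re-filters.
#'
#' @param pos,neg Raw [peak_table]s for the two polarities.
#' @param rsd_threshold_pct QC RSD filter threshold, percent.
#' @param impute_args,correct_args Argument lists passed on to
#'   [impute_missing()] and [qc_drift_correct()].
#' @return A list: `scaled` (bound autoscaled table), `raw` (bound
#'   corrected/averaged, unscaled table), `reports` (per-polarity QC
#'   reports), `models` (per-polarity correction models).
#' @export
run_pretreatment <- function(pos, neg, rsd_threshold_pct = 30,
                             impute_args = list(), correct_args = list()) {
  one <- function(tab) {
    tab <- do.call(impute_missing, c(list(table = tab), impute_args))
    corr <- do.call(qc_drift_correct, c(list(table = tab), correct_args))
    filt <- rsd_filter(corr$table, threshold_pct = rsd_threshold_pct)
    avg <- average_technical(filt$table)
    list(raw = avg, scaled = autoscale(avg),
         correction_report = corr$report, rsd_report = filt$report,
         model = corr$model)
  }
  p <- one(pos); n <- one(neg)
  list(scaled = bind_polarities(p$scaled, n$scaled),
       raw = bind_polarities(p$raw, n$raw),
       reports = list(pos_correction = p$correction_report,
                      neg_correction = n$correction_report,
                      pos_rsd = p$rsd_report, neg_rsd = n$rsd_report),
       models = list(pos = p$model, neg = n$model))
}
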