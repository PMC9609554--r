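#' Configure a synthetic profiling study
#'
#' Collects every knob of the generative model behind [simulate_study()].
#' The defaults state the world the package is tested against: the
#' 18-cultivar hop design ([study_design()]), ~3000 features split over two
#' polarities, 20 planted group markers at a one log2-unit shift, lognormal
#' biological and technical variation, smooth monotone within-batch drift
#' with batch offsets, and intensity-censored missingness.
#'
#' Intensity model, all on log2 scale: a feature's baseline is
#' `N(base_log_mean, base_log_sd)`; cultivar and biological-replicate
#' effects add `N(0, cultivar_log_sd)` and `N(0, bio_log_sd)`; planted
#' markers shift by `+marker_log2_effect/2` in latent group 1 and
#' `-marker_log2_effect/2` in group 2 (group difference =
#' `marker_log2_effect`, markers up in group 1). Every injection then
#' passes through the drift curve, its batch offset and multiplicative
#' `N(0, noise_log_sd)` noise. Pooled QC injections start from the
#' raw-scale mean of all study-sample abundances (ideal pooling, pre-noise)
#' and are subjected to the same drift and noise; blanks sit at 0.1% of the
#' feature baseline.
#'
#' @param design A [study_design()].
#' @param n_features_pos,n_features_neg Features per polarity table.
#' @param n_markers Number of planted group-discriminative features.
#' @param marker_log2_effect Group-mean shift of markers, log2 units.
#' @param base_log_mean,base_log_sd Location/scale of feature baselines
#'   (log2 peak area).
#' @param cultivar_log_sd,bio_log_sd Between-cultivar and
#'   between-biological-replicate SDs (log2).
#' @param noise_log_sd Within-injection multiplicative noise SD (log2).
#' @param drift_amplitude Relative intensity change over one batch (0.3 =
#'   30%); per-feature direction is random with 20% amplitude jitter.
#' @param batch_offset_sd SD of per-batch multiplicative offsets (log2).
#' @param missing_rate Target overall fraction of missing cells.
#' @param censor_strength How strongly missingness concentrates at low
#'   intensity (0 = completely at random).
#' @param group_split Optional named integer vector mapping cultivar name to
#'   latent group 1 or 2. Default: first half of the cultivars in group 1.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = study_design(),
                              n_features_pos = 1500, n_features_neg = 1500,
                              n_markers = 20, marker_log2_effect = 1.0,
                              base_log_mean = 17, base_log_sd = 2,
                              cultivar_log_sd = 0.5, bio_log_sd = 0.25,
                              noise_log_sd = 0.2,
                              drift_amplitude = 0.3, batch_offset_sd = 0.1,
                              missing_rate = 0.05, censor_strength = 3,
                              group_split = NULL, seed = 1) {
  stopifnot(inherits(design, "study_design"),
            n_features_pos >= 1, n_features_neg >= 1,
            n_markers >= 0, missing_rate >= 0, missing_rate <= 1,
            censor_strength >= 0, noise_log_sd >= 0,
            drift_amplitude >= 0, batch_offset_sd >= 0)
  if (n_markers > n_features_pos + n_features_neg)
    stop("n_markers (", n_markers, ") exceeds total feature count (",
         n_features_pos + n_features_neg, ")")
  if (!is.null(group_split)) {
    if (!all(group_split %in% c(1L, 2L)))
      stop("group_split values must be 1 or 2")
  }
  structure(
    list(design = design, n_features_pos = n_features_pos,
         n_features_neg = n_features_neg, n_markers = n_markers,
         marker_log2_effect = marker_log2_effect,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         cultivar_log_sd = cultivar_log_sd, bio_log_sd = bio_log_sd,
         noise_log_sd = noise_log_sd, drift_amplitude = drift_amplitude,
         batch_offset_sd = batch_offset_sd, missing_rate = missing_rate,
         censor_strength = censor_strength, group_split = group_split,
         seed = as.integer(seed)),
    class = "simulation_config")
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "", x)

# default cultivar names and latent-group split for a design
sim_cultivar_groups <- function(config) {
  d <- config$design
  if (!is.null(config$group_split)) {
    cultivars <- names(config$group_split)
    if (length(cultivars) != d$n_cultivars)
      stop("group_split must name all ", d$n_cultivars, " cultivars")
    groups <- as.integer(config$group_split)
  } else if (!is.null(d$cultivar_annotations) &&
             "new_label" %in% names(d$cultivar_annotations)) {
    cultivars <- d$cultivar_annotations$cultivar
    groups <- as.integer(d$cultivar_annotations$new_label)
  } else {
    cultivars <- sprintf("Cultivar%02d", seq_len(d$n_cultivars))
    groups <- ifelse(seq_len(d$n_cultivars) <= ceiling(d$n_cultivars / 2), 1L, 2L)
  }
  stats::setNames(groups, cultivars)
}

# injection layout for one simulated run: rows in global injection order
sim_layout <- function(design, cultivars) {
  n_samp <- design$n_cultivars * design$n_bio
  per_batch <- n_samp / design$n_batches
  samp <- tidyr::expand_grid(cultivar = cultivars,
                             bio_rep = seq_len(design$n_bio))
  samp <- samp[sample.int(nrow(samp)), ]          # randomize over batches
  samp$batch <- rep(seq_len(design$n_batches), each = per_batch)
  rows <- list()
  for (b in seq_len(design$n_batches)) {
    sb <- samp[samp$batch == b, ]
    study <- tidyr::expand_grid(i = seq_len(nrow(sb)),
                                tech_rep = seq_len(design$n_tech))
    batch_rows <- dplyr::bind_rows(
      tibble::tibble(role = "study",
                     cultivar = sb$cultivar[study$i],
                     bio_rep = sb$bio_rep[study$i],
                     tech_rep = study$tech_rep),
      tibble::tibble(role = rep("qc", design$qc_per_batch),
                     cultivar = NA_character_, bio_rep = NA_integer_,
                     tech_rep = NA_integer_),
      tibble::tibble(role = rep("blank", design$blank_per_batch),
                     cultivar = NA_character_, bio_rep = NA_integer_,
                     tech_rep = NA_integer_))
    batch_rows <- batch_rows[sample.int(nrow(batch_rows)), ]
    batch_rows$batch <- b
    batch_rows$batch_pos <- seq_len(nrow(batch_rows))
    rows[[b]] <- batch_rows
  }
  out <- dplyr::bind_rows(rows)
  out$injection_order <- seq_len(nrow(out))
  out$sample_id <- NA_character_
  is_study <- out$role == "study"
  out$sample_id[is_study] <- sprintf("S_%s_b%d_t%d",
                                     sanitize_id(out$cultivar[is_study]),
                                     out$bio_rep[is_study],
                                     out$tech_rep[is_study])
  out$sample_id[out$role == "qc"] <- sprintf("QC_%02d", seq_len(sum(out$role == "qc")))
  out$sample_id[out$role == "blank"] <- sprintf("BL_%02d", seq_len(sum(out$role == "blank")))
  out
}

# one polarity's intensity matrix plus per-feature truth pieces
sim_polarity <- function(config, layout, prefix, n_features, marker_flag,
                         groups) {
  d <- config$design
  n_inj <- nrow(layout)
  cultivars <- names(groups)
  feat <- tibble::tibble(
    feature_id = sprintf("%s%04d", prefix, seq_len(n_features)),
    mz = stats::runif(n_features, 120, 850),
    rt = stats::runif(n_features, 0.5, 30),
    polarity = if (prefix == "P") "positive" else "negative")
  base <- stats::rnorm(n_features, config$base_log_mean, config$base_log_sd)
  # cultivar and biological effects, log2
  cult_eff <- matrix(stats::rnorm(d$n_cultivars * n_features,
                                  0, config$cultivar_log_sd),
                     d$n_cultivars, n_features,
                     dimnames = list(cultivars, NULL))
  bio_eff <- array(stats::rnorm(d$n_cultivars * d$n_bio * n_features,
                                0, config$bio_log_sd),
                   dim = c(d$n_cultivars, d$n_bio, n_features),
                   dimnames = list(cultivars, NULL, NULL))
  shift <- ifelse(groups == 1L, 0.5, -0.5)  # markers up in group 1
  # sample-level (cultivar x bio) log2 abundances
  samp_grid <- tidyr::expand_grid(cultivar = cultivars, bio_rep = seq_len(d$n_bio))
  log_ab <- matrix(0, nrow(samp_grid), n_features)
  for (i in seq_len(nrow(samp_grid))) {
    cv <- samp_grid$cultivar[i]; br <- samp_grid$bio_rep[i]
    log_ab[i, ] <- base + cult_eff[cv, ] + bio_eff[cv, br, ] +
      ifelse(marker_flag, shift[cv] * config$marker_log2_effect, 0)
  }
  raw_ab <- 2^log_ab
  qc_ab <- colMeans(raw_ab)                 # ideal pooling, pre-noise
  blank_ab <- 2^base * 1e-3
  # drift: monotone exponential within batch, per-feature sign + jitter
  amp <- config$drift_amplitude * stats::runif(n_features, 0.8, 1.2)
  sgn <- sample(c(-1, 1), n_features, replace = TRUE)
  per_batch_len <- n_inj / d$n_batches
  frac <- if (per_batch_len > 1) (layout$batch_pos - 1) / (per_batch_len - 1) else 0
  drift <- exp(outer(frac, sgn * log1p(amp)))          # n_inj x n_features
  batch_offsets <- 2^stats::rnorm(d$n_batches, 0, config$batch_offset_sd)
  key <- paste(samp_grid$cultivar, samp_grid$bio_rep)
  row_ab <- matrix(0, n_inj, n_features)
  for (r in seq_len(n_inj)) {
    row_ab[r, ] <- switch(layout$role[r],
      study = raw_ab[match(paste(layout$cultivar[r], layout$bio_rep[r]), key), ],
      qc = qc_ab,
      blank = blank_ab)
  }
  noise <- matrix(2^stats::rnorm(n_inj * n_features, 0, config$noise_log_sd),
                  n_inj, n_features)
  m <- row_ab * drift * batch_offsets[layout$batch] * noise
  samples <- layout[, c("sample_id", "role", "cultivar", "bio_rep",
                        "tech_rep", "batch", "injection_order")]
  list(table = peak_table(m, samples, feat),
       drift = t(drift), batch_offsets = batch_offsets)
}

#' Simulate a two-polarity untargeted profiling study with ground truth
#'
#' Generates positive- and negative-mode peak tables following the layout
#' and generative model described in [simulation_config()], together with a
#' `simulation_truth` record of what was planted: marker feature ids
#' (namespaced `pos_`/`neg_` as [bind_polarities()] will name them), the
#' cultivar-to-group mapping, per-feature drift curves evaluated at each
#' injection order, and per-batch offsets.
#'
#' Study samples are randomized over batches; each batch holds every one of
#' its study samples injected `n_tech` times plus the configured QC and
#' blank injections, in randomized within-batch order. Both polarity tables
#' share the injection layout (as the two acquisition modes of one run do)
#' but have independent features.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `pos` and `neg` ([peak_table]s) and
#'   `truth` (`simulation_truth`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- sim_cultivar_groups(config)
  layout <- sim_layout(config$design, names(groups))
  n_tot <- config$n_features_pos + config$n_features_neg
  marker_idx <- sample.int(n_tot, config$n_markers)
  flag_pos <- seq_len(config$n_features_pos) %in% marker_idx
  flag_neg <- (config$n_features_pos + seq_len(config$n_features_neg)) %in% marker_idx
  pos <- sim_polarity(config, layout, "P", config$n_features_pos, flag_pos, groups)
  neg <- sim_polarity(config, layout, "N", config$n_features_neg, flag_neg, groups)
  if (config$missing_rate > 0) {
    pos$table <- inject_missing(pos$table, config$missing_rate,
                                config$censor_strength,
                                seed = sample.int(2^30, 1))
    neg$table <- inject_missing(neg$table, config$missing_rate,
                                config$censor_strength,
                                seed = sample.int(2^30, 1))
  }
  marker_ids <- c(paste0("pos_", pos$table$features$feature_id[flag_pos]),
                  paste0("neg_", neg$table$features$feature_id[flag_neg]))
  drift_curve <- rbind(pos$drift, neg$drift)
  rownames(drift_curve) <- c(paste0("pos_", pos$table$features$feature_id),
                             paste0("neg_", neg$table$features$feature_id))
  truth <- structure(
    list(marker_ids = marker_ids, group_of_cultivar = groups,
         drift_curve = drift_curve, batch_offsets = pos$batch_offsets,
         batch_offsets_neg = neg$batch_offsets),
    class = "simulation_truth")
  list(pos = pos$table, neg = neg$table, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d planted markers; %d cultivars (%d in group 1)\n",
              length(x$marker_ids), length(x$group_of_cultivar),
              sum(x$group_of_cultivar == 1L)))
  invisible(x)
}

#' Inject missing values into a peak table
#'
#' Blanks out cells of an unscaled peak table at an overall target rate,
#' with the probability of removal non-increasing in intensity when
#' `censor_strength > 0` (left-censoring, the dominant missingness mode of
#' peak-picked LC-MS data). Exactly `round(rate * n_cells)` cells are
#' removed, drawn without replacement with weight
#' `exp(-censor_strength * z)` where `z` is the standardized log2
#' intensity. The highest-intensity cell of each feature is never removed,
#' so no feature becomes fully missing.
#'
#' @param table An unscaled [peak_table].
#' @param rate Target overall missing fraction in `[0, 1]`.
#' @param censor_strength Non-negative; 0 gives missing-completely-at-random.
#' @param seed Integer seed.
#' @return The table with missing markers (`NA`) injected.
#' @export
inject_missing <- function(table, rate, censor_strength = 0, seed = 1) {
  validate_peak_table(table)
  if (table$scaled) stop("inject_missing requires an unscaled table")
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(table)
  set.seed(seed)
  m <- table$intensities
  obs <- which(!is.na(m) & m > 0)
  n_remove <- round(rate * length(m))
  # protect each feature's single largest observed cell
  guard <- vapply(seq_len(ncol(m)), function(j) {
    col_obs <- which(!is.na(m[, j]))
    (j - 1L) * nrow(m) + col_obs[which.max(m[col_obs, j])]
  }, integer(1))
  cand <- setdiff(obs, guard)
  n_remove <- min(n_remove, length(cand))
  z <- log2(m[cand])
  z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
  w <- exp(-censor_strength * z)
  holes <- sample(cand, n_remove, prob = w)
  m[holes] <- NA_real_
  out <- table
  out$intensities <- m
  out
}
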