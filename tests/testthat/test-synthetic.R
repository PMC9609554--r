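test_that("the degenerate generative model collapses as it should", {
  cfg <- small_config(n_feat = 12, n_markers = 0, marker_log2_effect = 0,
                      bio_log_sd = 0, noise_log_sd = 0, drift_amplitude = 0,
                      batch_offset_sd = 0, missing_rate = 0)
  sim <- simulate_study(cfg)
  m <- sim$pos$intensities
  s <- sim$pos$samples
  # all study rows of one cultivar identical
  for (cv in unique(stats::na.omit(s$cultivar))) {
    rows <- m[s$role == "study" & s$cultivar == cv, , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(v) diff(range(v)))), 1e-9)
  }
  # every QC row equals the mean of all study rows
  study_mean <- colMeans(m[s$role == "study", , drop = FALSE])
  for (r in which(s$role == "qc")) {
    expect_equal(unname(m[r, ]), unname(study_mean), tolerance = 1e-12)
  }
})

test_that("the emulated design yields the published injection arithmetic", {
  sim <- simulate_study(small_config(n_feat = 5))
  for (tab in list(sim$pos, sim$neg)) {
    roles <- table(tab$samples$role)
    expect_equal(as.integer(roles[["study"]]), 108L)  # 18 cultivars x 3 bio x 2 tech
    expect_equal(as.integer(roles[["qc"]]), 45L)      # 5 per batch x 9 batches
    expect_equal(as.integer(roles[["blank"]]), 27L)   # 3 per batch x 9 batches
    expect_equal(sort(tab$samples$injection_order), 1:180)
    expect_equal(as.integer(table(tab$samples$batch)), rep(20L, 9))
    # both technical replicates of a sample sit in the same batch
    st <- tab$samples[tab$samples$role == "study", ]
    by_sample <- split(st$batch, paste(st$cultivar, st$bio_rep))
    expect_true(all(vapply(by_sample, function(b) length(unique(b)) == 1,
                           logical(1))))
  }
})

test_that("planted marker effects match their nominal log2 shift", {
  cfg <- small_config(n_feat = 50, n_markers = 10, marker_log2_effect = 1,
                      drift_amplitude = 0, batch_offset_sd = 0,
                      missing_rate = 0, seed = 8)
  sim <- simulate_study(cfg)
  bound <- bind_polarities(sim$pos, sim$neg)
  labels <- sim$truth$group_of_cultivar[bound$samples$cultivar]
  g1 <- which(labels == 1); g2 <- which(labels == 2)
  lg <- log2(bound$intensities)
  diffs <- colMeans(lg[g1, sim$truth$marker_ids, drop = FALSE]) -
    colMeans(lg[g2, sim$truth$marker_ids, drop = FALSE])
  # empirical group difference of the mean marker shift vs nominal 1.0
  se_mean <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.0), 3 * max(se_mean, 0.02))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- small_config(n_feat = 8, missing_rate = 0.05)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$pos$intensities, b$pos$intensities)
  expect_identical(a$neg$samples, b$neg$samples)
  expect_identical(a$truth$marker_ids, b$truth$marker_ids)
  c <- simulate_study(small_config(n_feat = 8, missing_rate = 0.05, seed = 2))
  expect_false(identical(a$pos$samples$cultivar, c$pos$samples$cultivar))
})

test_that("QC pooling reduces feature-wise RSD relative to study samples", {
  sim <- simulate_study(small_config(n_feat = 60, n_markers = 0,
                                     drift_amplitude = 0, batch_offset_sd = 0,
                                     seed = 3))
  m <- sim$pos$intensities
  s <- sim$pos$samples
  rsd <- function(v) stats::sd(v) / mean(v) * 100
  qc_rsd <- apply(m[s$role == "qc", ], 2, rsd)
  study_rsd <- apply(m[s$role == "study", ], 2, rsd)
  expect_lt(stats::median(qc_rsd), stats::median(study_rsd))
})

test_that("blank injections sit far below study intensities", {
  sim <- simulate_study(small_config(n_feat = 30, seed = 4, missing_rate = 0))
  m <- sim$pos$intensities
  s <- sim$pos$samples
  expect_lt(stats::median(m[s$role == "blank", ]),
            0.01 * stats::median(m[s$role == "study", ]))
})

test_that("inject_missing hits its target rate and censors low intensities", {
  sim <- simulate_study(small_config(n_feat = 50, missing_rate = 0, seed = 5))
  tab <- sim$pos
  expect_identical(inject_missing(tab, 0, seed = 1), tab)
  expect_error(inject_missing(tab, 1.2, seed = 1), "rate")

  mcar <- inject_missing(tab, 0.1, censor_strength = 0, seed = 2)
  frac <- mean(is.na(mcar$intensities))
  expect_gte(frac, 0.09); expect_lte(frac, 0.11)

  cens <- inject_missing(tab, 0.1, censor_strength = 5, seed = 3)
  mask <- is.na(cens$intensities)
  expect_lt(mean(tab$intensities[mask]), mean(tab$intensities[!mask]))
  # no feature loses all its observations
  expect_true(all(colSums(!is.na(cens$intensities)) > 0))
})

test_that("config validation rejects impossible marker counts", {
  expect_error(small_config(n_feat = 5, n_markers = 11), "exceeds")
})
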