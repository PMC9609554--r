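test_that("imputation is the identity on complete tables and recovers constants", {
  set.seed(1)
  tab <- make_table(matrix(stats::rlnorm(40, 5, 1), 8, 5),
                    roles = c(rep("study", 6), "qc", "qc"),
                    cultivar = c(rep("A", 6), NA, NA),
                    bio_rep = c(1:6, NA, NA))
  expect_identical(impute_missing(tab, seed = 1), tab)

  # constant feature with one hole among uninformative companions
  m <- cbind(rep(100, 12), matrix(stats::runif(36, 1, 2), 12, 3))
  tab2 <- make_table(m, roles = c(rep("study", 10), "qc", "qc"),
                     cultivar = c(rep("A", 10), NA, NA),
                     bio_rep = c(1:10, NA, NA))
  tab2$intensities[3, 1] <- NA
  out <- impute_missing(tab2, seed = 2)
  expect_equal(out$intensities[3, 1], 100, tolerance = 1e-8)
  # observed cells untouched
  expect_identical(out$intensities[-3, ], tab2$intensities[-3, ])

  # fully missing feature is a named error
  tab3 <- tab2
  tab3$intensities[, 2] <- NA
  expect_error(impute_missing(tab3), "F002")
})

test_that("tree-ensemble imputation beats feature-mean imputation on NRMSE", {
  sim <- simulate_study(small_config(n_feat = 40, seed = 6, missing_rate = 0))
  truth <- sim$pos
  holed <- inject_missing(truth, 0.10, censor_strength = 0, seed = 7)
  mask <- is.na(holed$intensities)
  forest <- impute_missing(holed, seed = 8)
  means <- impute_missing(holed, seed = 8, regressor = "mean")
  err_forest <- nrmse(forest$intensities, truth$intensities, mask)
  err_mean <- nrmse(means$intensities, truth$intensities, mask)
  expect_lt(err_forest, err_mean)
})

test_that("the correction equation maps model-matched cells to 1000", {
  # constant QC series: any interpolating model predicts the constant
  m <- matrix(c(100, 100, 100, 200,
                50, 50, 50, 75), 4, 2)
  tab <- make_table(m, roles = c("qc", "qc", "qc", "study"),
                    cultivar = c(NA, NA, NA, "A"),
                    bio_rep = c(NA, NA, NA, 1L))
  res <- qc_drift_correct(tab)
  # QC cells: observed equals prediction -> exactly 1000
  expect_equal(unname(res$table$intensities[1:3, 1]), rep(1000, 3))
  # study cell at twice the QC level -> 2000
  expect_equal(res$table$intensities[4, 1], 2000)
  # 75 on a constant-50 feature -> 1500
  expect_equal(res$table$intensities[4, 2], 1500)
  expect_error(qc_drift_correct(make_table(m[1:2, ], roles = c("qc", "qc"))),
               ">= 3 QC")
})

test_that("drift correction reduces QC RSD on drifting data", {
  sim <- simulate_study(small_config(n_feat = 50, seed = 9,
                                     drift_amplitude = 0.4))
  res <- qc_drift_correct(sim$pos)
  expect_lte(stats::median(res$report$rsd_after),
             stats::median(res$report$rsd_before))
  # report is internally consistent with a direct recomputation
  qc <- sim$pos$samples$role == "qc"
  direct <- apply(sim$pos$intensities[qc, ], 2,
                  function(v) stats::sd(v) / mean(v) * 100)
  expect_equal(res$report$rsd_before, unname(direct), tolerance = 1e-12)
})

test_that("tree-based correction is scale-equivariant per feature", {
  sim <- simulate_study(small_config(n_feat = 10, seed = 10))
  tab <- sim$pos
  res1 <- qc_drift_correct(tab)
  tab2 <- tab
  tab2$intensities[, 3] <- tab$intensities[, 3] * 7.5
  res2 <- qc_drift_correct(tab2)
  expect_equal(res2$table$intensities[, 3], res1$table$intensities[, 3],
               tolerance = 1e-9)
})

test_that("rsd_filter removes irreproducible features and keeps constants", {
  m <- rbind(c(100, 50, 10), c(200, 50, 0), c(300, 50, 0))
  tab <- make_table(m, roles = rep("qc", 3))
  res <- rsd_filter(tab, threshold_pct = 30)
  # (100,200,300): sd 100, mean 200 -> RSD 50% -> removed
  expect_equal(res$report$rsd[1], 50)
  expect_false(res$report$retained[1])
  # identical QC values -> RSD 0 -> retained
  expect_equal(res$report$rsd[2], 0)
  expect_true(res$report$retained[2])
  expect_equal(res$table$features$feature_id, "F002")

  # surviving set equals an independent recount on a seeded table
  sim <- simulate_study(small_config(n_feat = 60, seed = 11))
  filt <- rsd_filter(sim$pos, threshold_pct = 25)
  qc <- sim$pos$intensities[sim$pos$samples$role == "qc", ]
  keep <- vapply(seq_len(ncol(qc)), function(j) {
    mu <- mean(qc[, j])
    mu != 0 && stats::sd(qc[, j]) / mu * 100 <= 25
  }, logical(1))
  expect_setequal(filt$table$features$feature_id,
                  sim$pos$features$feature_id[keep])
})

test_that("a zero-mean QC feature is flagged and removed, not fatal", {
  m <- rbind(c(0, 5), c(0, 5), c(0, 5))
  tab <- make_table(m, roles = rep("qc", 3))
  res <- rsd_filter(tab)
  expect_true(is.na(res$report$rsd[1]))
  expect_false(res$report$retained[1])
  expect_equal(n_features(res$table), 1)
})

test_that("technical averaging produces one row per biological sample", {
  m <- rbind(c(10), c(20), c(7), c(99))
  tab <- make_table(m, roles = c("study", "study", "study", "qc"),
                    cultivar = c("A", "A", "B", NA),
                    bio_rep = c(1L, 1L, 1L, NA),
                    tech_rep = c(1L, 2L, 1L, NA))
  avg <- average_technical(tab)
  expect_equal(n_samples(avg), 2)
  expect_equal(unname(avg$intensities[, 1]), c(15, 7))  # mean(10,20); single passes
  expect_true(all(is.na(avg$samples$injection_order)))
  expect_true(all(is.na(avg$samples$batch)))

  # emulated full design collapses to the published 54 analysis samples
  sim <- simulate_study(small_config(n_feat = 4, seed = 12))
  expect_equal(n_samples(average_technical(sim$pos)), 54)
})

test_that("autoscale centres, scales, drops constants and inverts cleanly", {
  set.seed(13)
  m <- cbind(matrix(stats::rlnorm(30, 3, 1), 10, 3), rep(4, 10))
  tab <- make_table(m, roles = rep("study", 10),
                    cultivar = rep(c("A", "B"), 5), bio_rep = rep(1:5, each = 2))
  expect_warning(scaled <- autoscale(tab), "zero-variance")
  expect_equal(n_features(scaled), 3)
  expect_true(all(abs(colMeans(scaled$intensities)) < 1e-10))
  expect_true(all(abs(apply(scaled$intensities, 2, stats::sd) - 1) < 1e-10))
  expect_true(scaled$scaled)
  back <- unscale(scaled)
  expect_equal(back$intensities, tab$intensities[, 1:3], tolerance = 1e-10)
})

test_that("the pre-treatment chain composes into the analysis-ready table", {
  sim <- simulate_study(small_config(n_feat = 25, seed = 14,
                                     missing_rate = 0.02))
  pre <- run_pretreatment(sim$pos, sim$neg)
  expect_equal(n_samples(pre$scaled), 54)
  expect_true(pre$scaled$scaled)
  expect_false(pre$raw$scaled)
  expect_false(anyNA(pre$scaled$intensities))
  expect_true(all(pre$raw$intensities > 0))
  expect_identical(pre$scaled$samples$sample_id, pre$raw$samples$sample_id)
  # scaled and raw tables carry the same feature set
  expect_identical(pre$scaled$features$feature_id, pre$raw$features$feature_id)
})
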