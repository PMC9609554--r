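test_that("stratified bootstrap keeps size, classes and the 0.632 law", {
  idx <- 1:200
  labels <- rep(c("a", "b"), each = 100)
  set.seed(1)
  n_draws <- 10000
  uniq_a <- uniq_b <- numeric(n_draws)
  for (r in seq_len(n_draws)) {
    bs <- bootstrap_resample(idx, labels)
    if (r <= 50) {
      expect_length(bs, 200)
      expect_setequal(unique(labels[bs]), c("a", "b"))
    }
    uniq_a[r] <- length(unique(bs[bs <= 100])) / 100
    uniq_b[r] <- length(unique(bs[bs > 100])) / 100
  }
  # E[unique fraction] = 1 - (1 - 1/n)^n -> 1 - e^-1
  expect_lt(abs(mean(uniq_a) - (1 - exp(-1))), 0.01)
  expect_lt(abs(mean(uniq_b) - (1 - exp(-1))), 0.01)
  expect_error(bootstrap_resample(1:10, rep("a", 10)), "both classes")
})

test_that("the rational cut-off is the intersection of its three criteria", {
  set.seed(2)
  n <- 30
  labels <- rep(c(1, 2), each = n / 2)
  raw <- matrix(stats::rlnorm(n * 40, 8, 0.4), n, 40,
                dimnames = list(NULL, sprintf("F%02d", 1:40)))
  raw[labels == 1, 1:5] <- raw[labels == 1, 1:5] * 2^2.5  # planted block
  scaled <- scale(raw)
  # t-test + fold-change only (VIP disabled): equals the two direct filters
  crit_tf <- cutoff_criteria(vip_threshold = -1)
  got <- rational_cutoff(scaled, raw, labels, crit_tf)
  mt <- moderated_t_test(log2(raw), factor(labels))
  t_set <- mt$table$feature[mt$table$p_adjusted < 0.05]
  fc_set <- names(which(abs(log_fold_change(raw, factor(labels))) > 1))
  expect_setequal(got, intersect(t_set, fc_set))

  # VIP-only criterion against a direct recomputation on an aligned RNG
  crit_v <- cutoff_criteria(alpha_adjusted = 1, fc_threshold = -Inf)
  set.seed(77)
  got_v <- rational_cutoff(scaled, raw, labels, crit_v)
  set.seed(77)
  tuned <- tune_pls_components(scaled, factor(labels), max_components = 5,
                               n_folds = 10)
  fit <- fit_pls(scaled, factor(labels), tuned$n_components)
  expect_setequal(got_v, names(which(vip_scores(fit) > 1)))

  # a feature with an extreme planted effect always survives the full cut-off
  full <- rational_cutoff(scaled, raw, labels, cutoff_criteria())
  expect_true(all(sprintf("F%02d", 1:5) %in% full))
  expect_error(rational_cutoff(scaled, raw, rep(1, n)), "both classes")
})

test_that("pure noise passes the three simultaneous criteria almost nowhere", {
  set.seed(3)
  n <- 30
  raw <- matrix(stats::rlnorm(n * 200, 8, 0.4), n, 200,
                dimnames = list(NULL, sprintf("F%03d", 1:200)))
  got <- rational_cutoff(scale(raw), raw, rep(c(1, 2), each = 15))
  expect_lte(length(got), 5)
})

test_that("held-out GLM validation scores what a confusion recount scores", {
  set.seed(4)
  x <- matrix(stats::rnorm(60), 60, 1)
  y <- ifelse(x[, 1] > 0, "a", "b")              # perfectly discriminative
  expect_equal(glm_validate(x[1:40, , drop = FALSE], y[1:40],
                            x[41:60, , drop = FALSE], y[41:60]), 1)
  expect_error(glm_validate(x[1:40, 0, drop = FALSE], y[1:40],
                            x[41:60, 0, drop = FALSE], y[41:60]), "empty")
  # accuracy equals a manual recount
  xn <- matrix(stats::rnorm(200 * 3), 200, 3)
  yn <- rep(c("a", "b"), 100)
  fit <- fit_logistic_glm(xn[1:100, ], yn[1:100])
  pred <- predict(fit, xn[101:200, ], type = "class")
  acc <- glm_validate(xn[1:100, ], yn[1:100], xn[101:200, ], yn[101:200])
  expect_equal(acc, sum(pred == yn[101:200]) / 100)
  # chance level when labels carry no information
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
})

test_that("nested selection is deterministic and closed under intersection", {
  sim <- simulate_study(small_config(n_feat = 50, n_markers = 6,
                                     marker_log2_effect = 2, seed = 15))
  pre <- run_pretreatment(sim$pos, sim$neg)
  labels <- sim$truth$group_of_cultivar[pre$scaled$samples$cultivar]
  sel1 <- run_nested_selection(pre$scaled, pre$raw, labels, seed = 15,
                               n_outer = 5, n_boot = 2)
  sel2 <- run_nested_selection(pre$scaled, pre$raw, labels, seed = 15,
                               n_outer = 5, n_boot = 2)
  expect_identical(sel1$outer_sets, sel2$outer_sets)
  expect_identical(sel1$final_set, sel2$final_set)
  expect_identical(sel1$outer_accuracies, sel2$outer_accuracies)
  for (s in sel1$outer_sets) expect_true(all(sel1$final_set %in% s))
})

test_that("the final set does not depend on feature column order", {
  sim <- simulate_study(small_config(n_feat = 40, n_markers = 5,
                                     marker_log2_effect = 2, seed = 16))
  pre <- run_pretreatment(sim$pos, sim$neg)
  labels <- sim$truth$group_of_cultivar[pre$scaled$samples$cultivar]
  sel1 <- run_nested_selection(pre$scaled, pre$raw, labels, seed = 16,
                               n_outer = 5, n_boot = 2)
  perm <- sample(seq_len(n_features(pre$scaled)))
  xs <- pre$scaled$intensities[, perm]
  xr <- pre$raw$intensities[, perm]
  sel2 <- run_nested_selection(xs, xr, labels, seed = 16,
                               n_outer = 5, n_boot = 2)
  expect_setequal(sel1$final_set, sel2$final_set)
})

test_that("raising the planted effect never lowers marker recall", {
  recalls <- vapply(c(1, 2.5), function(effect) {
    sim <- simulate_study(small_config(n_feat = 100, n_markers = 10,
                                       marker_log2_effect = effect, seed = 17))
    pre <- run_pretreatment(sim$pos, sim$neg)
    labels <- sim$truth$group_of_cultivar[pre$scaled$samples$cultivar]
    sel <- suppressWarnings(
      run_nested_selection(pre$scaled, pre$raw, labels, seed = 17,
                           n_outer = 5, n_boot = 2))
    mean(sim$truth$marker_ids %in% sel$final_set)
  }, numeric(1))
  expect_gte(recalls[2], recalls[1])
})

test_that("empty outer sets are flagged and propagate to an empty final set", {
  set.seed(18)
  n <- 20
  raw <- matrix(stats::rlnorm(n * 30, 8, 0.4), n, 30,
                dimnames = list(NULL, sprintf("F%02d", 1:30)))
  labels <- rep(c(1, 2), each = 10)
  w <- testthat::capture_warnings(
    sel <- run_nested_selection(scale(raw), raw, labels, n_outer = 5,
                                n_boot = 2, seed = 18))
  expect_true(any(grepl("empty selected set", w)))
  expect_true(any(grepl("final intersected marker set is empty", w)))
  expect_length(sel$final_set, 0)
  expect_true(any(is.na(sel$outer_accuracies)))
})
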