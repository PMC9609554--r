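test_that("validation enforces the core invariants", {
  tab <- make_table(matrix(1:6, 2, 3), roles = c("study", "qc"))
  expect_s3_class(validate_peak_table(tab), "peak_table")

  bad <- tab; bad$samples$sample_id <- c("a", "a")
  expect_error(validate_peak_table(bad), "duplicate sample_id")
  bad <- tab; bad$features$feature_id[2] <- "F001"
  expect_error(validate_peak_table(bad), "duplicate feature_id")
  bad <- tab; bad$intensities[1, 1] <- -5
  expect_error(validate_peak_table(bad), "negative intensity")
  bad <- tab; bad$samples$role[2] <- "pooled"
  expect_error(validate_peak_table(bad), "unknown sample role")
  bad <- tab; bad$samples$injection_order <- c(1L, 1L)
  expect_error(validate_peak_table(bad), "unique")
  bad <- tab; bad$features$mz[1] <- 90
  expect_error(validate_peak_table(bad), "instrument range")
  # role-conditional metadata
  bad <- tab; bad$samples$cultivar[1] <- NA
  expect_error(validate_peak_table(bad), "must carry cultivar")
  bad <- tab; bad$samples$cultivar[2] <- "X"
  expect_error(validate_peak_table(bad), "must not carry")
})

test_that("write/read round trip is the identity", {
  dir <- withr::local_tempdir()
  # minimal 2 x 1 table
  tab <- make_table(matrix(c(10, 20), 2, 1), roles = c("study", "qc"))
  path <- file.path(dir, "mini.csv")
  write_peak_table(tab, path)
  back <- read_peak_table(path)
  expect_equal(back$samples, tab$samples)
  expect_equal(back$features, tab$features)
  expect_equal(back$intensities, tab$intensities)

  # seeded 54 x 50 table: metadata exact, intensities within print precision
  set.seed(20)
  big <- make_table(matrix(stats::rlnorm(54 * 50, 11, 1), 54, 50),
                    roles = c(rep("study", 48), rep("qc", 4), rep("blank", 2)),
                    cultivar = c(rep(sprintf("C%02d", 1:16), each = 3), rep(NA, 6)),
                    bio_rep = c(rep(1:3, 16), rep(NA, 6)),
                    tech_rep = c(rep(1L, 48), rep(NA, 6)))
  path2 <- file.path(dir, "big.csv")
  write_peak_table(big, path2)
  back2 <- read_peak_table(path2)
  expect_identical(back2$samples, big$samples)
  expect_identical(back2$features$feature_id, big$features$feature_id)
  expect_equal(back2$features$mz, big$features$mz, tolerance = 1e-12)
  expect_equal(back2$intensities, big$intensities, tolerance = 1e-12)
})

test_that("missing cells survive a round trip as missing, never zero", {
  dir <- withr::local_tempdir()
  tab <- make_table(matrix(c(10, NA, 5, 7), 2, 2), roles = c("study", "qc"))
  path <- file.path(dir, "holes.csv")
  write_peak_table(tab, path)
  raw <- readLines(path)
  expect_true(any(grepl("NA", raw[3])))
  back <- read_peak_table(path)
  expect_identical(is.na(back$intensities), is.na(tab$intensities))
  expect_false(any(back$intensities == 0, na.rm = TRUE))

  # an empty cell in the file also becomes a missing marker
  raw[2] <- sub("^(([^,]*,){7})[^,]*", "\\1", raw[2])  # blank first feature cell
  writeLines(raw, path)
  back2 <- read_peak_table(path)
  expect_true(is.na(back2$intensities[1, 1]))
})

test_that("an empty-feature table writes a header-only metadata file", {
  dir <- withr::local_tempdir()
  tab <- peak_table(matrix(numeric(0), 2, 0),
                    samples = tibble::tibble(
                      sample_id = c("a", "b"), role = c("qc", "qc"),
                      cultivar = NA_character_, bio_rep = NA_integer_,
                      tech_rep = NA_integer_, batch = 1L,
                      injection_order = 1:2),
                    features = tibble::tibble(feature_id = character(0),
                                              mz = numeric(0), rt = numeric(0),
                                              polarity = character(0)))
  path <- file.path(dir, "empty.csv")
  write_peak_table(tab, path)
  back <- read_peak_table(path)
  expect_equal(n_features(back), 0)
  expect_equal(back$samples$sample_id, c("a", "b"))
})

test_that("bind_polarities aligns by sample id and namespaces features", {
  set.seed(5)
  pos <- make_table(matrix(stats::runif(6, 1, 10), 3, 2),
                    roles = c("study", "study", "qc"))
  neg <- make_table(matrix(stats::runif(9, 1, 10), 3, 3),
                    roles = c("study", "study", "qc"), polarity = "negative")
  bound <- bind_polarities(pos, neg)
  expect_equal(n_features(bound), 5)
  expect_equal(bound$features$feature_id,
               c(paste0("pos_", pos$features$feature_id),
                 paste0("neg_", neg$features$feature_id)))
  # alignment by id, not row position
  neg_rev <- neg
  neg_rev$intensities <- neg$intensities[3:1, , drop = FALSE]
  neg_rev$samples <- neg$samples[3:1, ]
  bound_rev <- bind_polarities(pos, neg_rev)
  expect_equal(bound_rev$intensities, bound$intensities)
  # every bound column equals its source column after prefix lookup
  for (j in seq_len(ncol(pos$intensities))) {
    expect_equal(bound$intensities[, paste0("pos_", pos$features$feature_id[j])],
                 unname(pos$intensities[, j]), ignore_attr = TRUE)
  }
  for (j in seq_len(ncol(neg$intensities))) {
    expect_equal(bound$intensities[, paste0("neg_", neg$features$feature_id[j])],
                 unname(neg$intensities[, j]), ignore_attr = TRUE)
  }
})

test_that("bind_polarities is symmetric up to column order and names asymmetries", {
  set.seed(6)
  pos <- make_table(matrix(stats::runif(4, 1, 10), 2, 2), roles = c("study", "qc"))
  neg <- make_table(matrix(stats::runif(4, 1, 10), 2, 2),
                    roles = c("study", "qc"), polarity = "negative")
  ab <- bind_polarities(pos, neg)
  ba <- bind_polarities(neg, pos)
  expect_setequal(ab$features$feature_id, ba$features$feature_id)
  expect_equal(ab$intensities[, ba$features$feature_id], ba$intensities)

  neg_bad <- neg
  neg_bad$samples$sample_id[1] <- "other"
  rownames(neg_bad$intensities) <- neg_bad$samples$sample_id
  expect_error(bind_polarities(pos, neg_bad), "other")
})
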