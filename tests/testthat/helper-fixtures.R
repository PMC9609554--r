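# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures exist.

# hand-built peak table with explicit metadata; intensities filled by row
make_table <- function(intensities, roles, cultivar = NULL, bio_rep = NULL,
                       tech_rep = NULL, batch = NULL, mz = NULL, rt = NULL,
                       polarity = "positive") {
  m <- as.matrix(intensities)
  n <- nrow(m); p <- ncol(m)
  is_study <- roles == "study"
  cultivar <- cultivar %||% ifelse(is_study, "CultivarA", NA_character_)
  bio_rep <- bio_rep %||% ifelse(is_study, seq_len(n), NA_integer_)
  tech_rep <- tech_rep %||% ifelse(is_study, 1L, NA_integer_)
  samples <- tibble::tibble(
    sample_id = sprintf("inj%02d", seq_len(n)),
    role = roles, cultivar = cultivar,
    bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep),
    batch = as.integer(batch %||% rep(1L, n)),
    injection_order = seq_len(n))
  features <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(p)),
    mz = mz %||% seq(150, 800, length.out = p),
    rt = rt %||% seq(1, 20, length.out = p),
    polarity = polarity)
  peak_table(m, samples, features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small study-shaped simulation (full 180-injection layout, few features)
small_config <- function(n_feat = 40, ...) {
  args <- list(...)
  defaults <- list(n_features_pos = n_feat, n_features_neg = n_feat,
                   n_markers = 6, marker_log2_effect = 2,
                   missing_rate = 0, seed = 1)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# brute-force Ward.D2 agglomeration oracle: closed-form "energy" cluster
# cost, recomputed from the raw squared dissimilarities at every step
brute_ward2 <- function(points, metric = "manhattan") {
  d2 <- as.matrix(stats::dist(points, method = metric))^2
  cost <- function(A, B) {
    nA <- length(A); nB <- length(B)
    mab <- mean(d2[A, B, drop = FALSE])
    maa <- sum(d2[A, A]) / (nA * nA)
    mbb <- sum(d2[B, B]) / (nB * nB)
    nA * nB / (nA + nB) * (2 * mab - maa - mbb)
  }
  cl <- as.list(seq_len(nrow(d2)))
  heights <- numeric(0)
  partitions <- list()
  while (length(cl) > 1) {
    m <- length(cl)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        cc <- cost(cl[[i]], cl[[j]])
        if (cc < best[1]) best <- c(cc, i, j)
      }
    }
    heights <- c(heights, sqrt(best[1]))
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
    partitions[[length(partitions) + 1L]] <-
      vapply(seq_len(nrow(d2)),
             function(k) which(vapply(cl, function(g) k %in% g, logical(1))),
             integer(1))
  }
  list(heights = heights, partitions = partitions)
}

# NRMSE of imputed values against the ground truth held out by the mask
nrmse <- function(imputed, truth, mask) {
  sqrt(mean((imputed[mask] - truth[mask])^2)) / stats::sd(truth[mask])
}
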