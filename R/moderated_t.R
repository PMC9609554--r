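#' Empirical-Bayes moderated two-group t-test
#'
#' Per-feature two-group comparison with variance shrinkage: each feature's
#' pooled residual variance \eqn{s^2} (on \eqn{d = n - 2} df) is shrunk
#' towards a prior \eqn{s_0^2} estimated from all features,
#'
#' \deqn{s^2_{post} = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#'
#' and the moderated statistic \eqn{t = \Delta / (\sqrt{1/n_1 + 1/n_2}\,
#' s_{post})} is referred to a t distribution on \eqn{d + d_0} df. The
#' prior \eqn{(d_0, s_0^2)} is obtained by moment-matching the scaled-F
#' marginal distribution of the log sample variances through the closed
#' digamma/trigamma equations; features with zero sample variance are
#' excluded from the moment estimation. If every feature has zero residual
#' variance the test falls back to the ordinary t with a warning.
#'
#' @param x Numeric matrix, samples x features, no missing values.
#' @param labels Two-group factor/vector, one per row of `x`; the first
#'   level is group 1 and `mean_difference` is group1 - group2.
#' @param prior_df Optional override of \eqn{d_0}: `0` reproduces the
#'   ordinary two-sample pooled t exactly, `Inf` fully shrinks.
#' @return A `moderated_test` object; `tidy()` gives the per-feature table
#'   (`feature`, `mean_difference`, `t_moderated`, `p_value`,
#'   `p_adjusted`, `s2_posterior`), `glance()` the prior `df_prior` and
#'   `s2_prior`.
#' @export
moderated_t_test <- function(x, labels, prior_df = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("moderated_t_test requires a complete matrix")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two groups")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  d <- n1 + n2 - 2
  rss <- colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!g1, , drop = FALSE] - rep(m2, each = n2))^2)
  s2 <- rss / d
  if (all(s2 == 0)) {
    warning("all features have zero residual variance; ordinary t returned")
    prior_df <- 0
  }
  if (is.null(prior_df)) {
    prior <- fit_f_dist(s2[s2 > 0], d)
    d0 <- prior$df_prior; s02 <- prior$s2_prior
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else mean(s2[s2 > 0])
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt((1 / n1 + 1 / n2) * s2_post)
  tmod <- ifelse(se == 0, 0, (m1 - m2) / se)
  df_total <- d + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tmod)) else
    2 * stats::pt(-abs(tmod), df = df_total)
  structure(
    list(table = tibble::tibble(
           feature = colnames(x) %||% paste0("V", seq_along(m1)),
           mean_difference = m1 - m2,
           t_moderated = tmod,
           p_value = p,
           p_adjusted = bh_adjust(p),
           s2_posterior = s2_post,
           s2_sample = s2),
         df_residual = d, df_prior = d0, s2_prior = s02,
         df_total = df_total, groups = levels(labels)),
    class = "moderated_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# moment-match a scaled-F marginal to sample variances s2 on d df:
# log s2 ~ log s0^2 + log F(d, d0); matches mean and variance of log s2
# through digamma/trigamma identities.
fit_f_dist <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess dispersion: infinite prior df; the prior variance is the
    # geometric mean of the sample variances, so a table of exactly equal
    # variances is a fixed point of the shrinkage
    return(list(df_prior = Inf, s2_prior = exp(mean(z))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, s2_prior = s02)
}

# Newton solve trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: with `m` tests and ordered
#' p-values `p(1) <= ... <= p(m)`, the adjusted value of `p(j)` is
#' `min over k >= j of min(1, m * p(k) / k)`. Order-preserving, idempotent,
#' never smaller than the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

#' Per-feature log2 fold change between two groups
#'
#' `log2(mean(group 1) / mean(group 2))` computed on positive intensities
#' (the corrected, unscaled table; a fold change on centred data is
#' undefined).
#'
#' @param x Numeric matrix of positive intensities, samples x features.
#' @param labels Two-group factor/vector; first level is group 1.
#' @return Named numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two groups")
  g1 <- labels == levels(labels)[1]
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  if (any(m1 <= 0) || any(m2 <= 0))
    stop("nonpositive group mean; fold change needs positive intensities")
  stats::setNames(log2(m1 / m2), colnames(x))
}

#' @export
print.moderated_test <- function(x, ...) {
  cat(sprintf("<moderated_test> %d features; groups %s vs %s\n",
              nrow(x$table), x$groups[1], x$groups[2]))
  cat(sprintf("  prior df %.3g, prior variance %.4g; %d features at adj. p < 0.05\n",
              x$df_prior, x$s2_prior, sum(x$table$p_adjusted < 0.05)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy moderated_test
#' @export
tidy.moderated_test <- function(x, ...) x$table

#' @method glance moderated_test
#' @export
glance.moderated_test <- function(x, ...) {
  tibble::tibble(df_prior = x$df_prior, s2_prior = x$s2_prior,
                 df_residual = x$df_residual, df_total = x$df_total,
                 n_significant = sum(x$table$p_adjusted < 0.05))
}
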