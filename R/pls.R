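#' Partial least squares (PLS1) by NIPALS
#'
#' Single-response NIPALS with X-deflation: for each component the X-weight
#' is the (normalized) covariance direction `w = X'y / |X'y|`, scores
#' `t = Xw`, X-loading `p = X't / t't`, y-loading `q = y't / t't`, after
#' which `X` is deflated by `t p'`. Per-component explained sum of squares
#' of `y` is `SSY_a = q_a^2 t_a't_a`. Components whose residual `X'y` or
#' score norm vanishes (rank exhaustion) are not extracted; fewer
#' components are returned with a warning.
#'
#' `X` is expected autoscaled (the pipeline's convention); the response is
#' centred internally. Class labels are coded +1 (group 1) / -1 (group 2)
#' before centring.
#'
#' @param x Numeric matrix, samples x features (scaled).
#' @param y Numeric response, or a two-level factor to be coded +1/-1.
#' @param n_components Number of latent components to extract.
#' @return A `pls_model`: weights `W`, loadings `P`, y-loadings `q`,
#'   scores `T`, per-component `ssy`, `r2y`, coefficient vector `b`.
#' @export
fit_pls <- function(x, y, n_components) {
  x <- as.matrix(x)
  y <- code_response(y)
  stopifnot(n_components >= 1)
  if (n_components > min(nrow(x) - 1, ncol(x)))
    stop("n_components exceeds min(samples - 1, features)")
  y_center <- mean(y)
  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center)
  yc <- y - y_center
  ssy_tot <- sum(yc^2)
  n_feat <- ncol(x)
  W <- P <- matrix(0, n_feat, n_components)
  Tm <- matrix(0, nrow(x), n_components)
  q <- ssy <- numeric(n_components)
  Xd <- xc; yd <- yc
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    p <- crossprod(Xd, tt) / tt2
    qa <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - qa * tt
    a_used <- a
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt
    q[a] <- qa; ssy[a] <- qa^2 * tt2
  }
  if (a_used < n_components) {
    warning("rank deficiency: extracted ", a_used, " of ", n_components,
            " components")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]; ssy <- ssy[seq_len(a_used)]
  }
  if (a_used == 0L) stop("no PLS component could be extracted (X'y = 0)")
  rownames(W) <- rownames(P) <- colnames(x)
  # regression vector on the centred scale: b = W (P'W)^-1 q
  b <- W %*% solve(crossprod(P, W), q)
  structure(
    list(n_components = a_used, W = W, P = P, q = q, scores = Tm,
         ssy = ssy, r2y = sum(ssy) / ssy_tot, b = drop(b),
         x_center = x_center, y_center = y_center, q2 = NA_real_),
    class = "pls_model")
}

code_response <- function(y) {
  if (is.factor(y) || is.character(y) || is.logical(y)) {
    y <- as.factor(y)
    if (nlevels(y) != 2) stop("factor response must have two levels")
    ifelse(y == levels(y)[1], 1, -1)
  } else {
    as.numeric(y)
  }
}

#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  x <- sweep(as.matrix(newdata), 2, object$x_center)
  if (is.null(n_components)) {
    return(drop(x %*% object$b) + object$y_center)
  }
  # predictions for each requested component count (columns)
  vapply(n_components, function(a) {
    ia <- seq_len(a)
    b <- object$W[, ia, drop = FALSE] %*%
      solve(crossprod(object$P[, ia, drop = FALSE],
                      object$W[, ia, drop = FALSE]), object$q[ia])
    drop(x %*% b) + object$y_center
  }, numeric(nrow(x)))
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a \rVert)^2 /
#'   \sum_a SSY_a}}
#'
#' where `p` is the feature count; consequently the mean of `VIP^2` is
#' exactly 1 for every fitted model.
#'
#' @param model A [fit_pls()] model.
#' @return Named non-negative numeric vector, one VIP per feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) stop("total explained SSY is zero")
  w2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), `/`)^2
  p <- nrow(model$W)
  drop(sqrt(p * (w2 %*% model$ssy) / sum(model$ssy)))
}

#' Tune the PLS component count by cross-validated Q2
#'
#' Stratified k-fold cross-validation over component counts `1..
#' max_components`: for each fold a model is fitted on the training part
#' and held-out samples are predicted with every component count;
#' `Q2_A = 1 - PRESS_A / TSS` where TSS uses the training-mean prediction.
#' The smallest count whose Q2 lies within `tol_q2` of the maximum is
#' chosen (a parsimony margin, as in common chemometrics practice, so
#' near-tied extra components are not kept). Optionally, a permutation test
#' refits the chosen model under `n_permutations` random relabelings and
#' reports `p = (1 + #{Q2_perm >= Q2_obs}) / (n_permutations + 1)`.
#'
#' @param x,y As in [fit_pls()].
#' @param max_components Largest component count tried (capped at
#'   `min(n - 2, p)` to keep every training fold feasible).
#' @param n_folds Cross-validation folds (must not exceed the sample count).
#' @param n_permutations Label permutations for the significance check
#'   (0 = skip).
#' @param tol_q2 Parsimony margin: the smallest component count whose Q2
#'   is within `tol_q2` of the maximum is chosen.
#' @return A list: `n_components`, `q2` (vector over counts), `q2_best`,
#'   `permutation_p` (`NA` if skipped).
#' @export
tune_pls_components <- function(x, y, max_components = 5, n_folds = 10,
                                n_permutations = 0, tol_q2 = 0.01) {
  x <- as.matrix(x)
  y <- code_response(y)
  n <- nrow(x)
  if (n_folds > n) stop("n_folds exceeds the sample count")
  max_components <- min(max_components, n - ceiling(n / n_folds) - 1, ncol(x))
  max_components <- max(max_components, 1)
  folds <- stratified_folds(factor(y > mean(y)), n_folds)
  q2 <- pls_cv_q2(x, y, folds, max_components)
  # parsimony: the smallest count within tol_q2 of the maximum; an extra
  # component must buy a real predictive gain to be kept
  best <- which(q2 >= max(q2) - tol_q2)[1]
  perm_p <- NA_real_
  if (n_permutations > 0) {
    obs <- q2[best]
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      yp <- sample(y)
      q2p <- tryCatch(pls_cv_q2(x, yp, stratified_folds(factor(yp > mean(yp)),
                                                        n_folds), best)[best],
                      error = function(e) -Inf)
      if (!is.na(q2p) && q2p >= obs) hits <- hits + 1L
    }
    perm_p <- (1 + hits) / (n_permutations + 1)
  }
  list(n_components = best, q2 = q2, q2_best = q2[best],
       permutation_p = perm_p)
}

# Q2 per component count, given fold assignment
pls_cv_q2 <- function(x, y, folds, max_components) {
  press <- tss <- numeric(max_components)
  for (f in sort(unique(folds))) {
    test <- folds == f
    a_max <- min(max_components, sum(!test) - 1, ncol(x))
    fit <- suppressWarnings(fit_pls(x[!test, , drop = FALSE], y[!test], a_max))
    a_avail <- min(fit$n_components, a_max)
    pred <- predict(fit, x[test, , drop = FALSE], n_components = seq_len(a_avail))
    if (!is.matrix(pred)) pred <- matrix(pred, nrow = sum(test))
    for (a in seq_len(max_components)) {
      pa <- pred[, min(a, a_avail)]
      press[a] <- press[a] + sum((y[test] - pa)^2)
      tss[a] <- tss[a] + sum((y[test] - mean(y[!test]))^2)
    }
  }
  1 - press / tss
}

# stratified fold ids: classes spread as evenly as possible; uses the
# current RNG stream
stratified_folds <- function(labels, n_folds) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  offset <- 0L
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((seq_along(idx) + offset - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d features; R2Y = %.3f\n",
              x$n_components, nrow(x$W), x$r2y))
  invisible(x)
}

#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(feature = rownames(x$W) %||% paste0("V", seq_len(nrow(x$W))),
                 vip = vip_scores(x),
                 coefficient = x$b)
}

#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, r2y = x$r2y, q2 = x$q2)
}
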