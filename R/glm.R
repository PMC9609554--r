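#' Ridge-penalized logistic regression via IRLS
#'
#' Two-class generalized linear model used for outer-fold validation.
#' Maximizes the penalized log-likelihood
#' \eqn{\ell(\beta) - \lambda/2 \sum_{j \ge 1} \beta_j^2} (the intercept is
#' not penalized) by iteratively reweighted least squares / Newton steps.
#' The small default ridge keeps the fit finite on perfectly separable
#' folds, which strong marker sets routinely produce.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Two-level factor/vector; the first level is coded 1.
#' @param ridge Non-negative penalty \eqn{\lambda}.
#' @param max_iter,tol Newton iteration cap and deviance-change tolerance.
#' @return A `logistic_glm` with `coefficients` (intercept first),
#'   `deviance`, `converged`. `predict()` gives probabilities
#'   (`type = "response"`) or 0/1 classes at probability 0.5
#'   (`type = "class"`).
#' @export
fit_logistic_glm <- function(x, y, ridge = 1e-3, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  yb <- binarize_labels(y)
  if (min(table(yb)) < 2) stop("each class needs >= 2 samples")
  X <- cbind(`(intercept)` = 1, x)
  pen <- diag(c(0, rep(ridge, ncol(x))), ncol(X))
  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, yb - mu) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    beta <- beta + solve(H, grad)
    eta <- drop(X %*% beta)
    # log(1 + e^eta) computed overflow-safe
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    dev <- -2 * sum(yb * eta - log1pe) + ridge * sum(beta[-1]^2)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (!converged && max_iter > 1)
    stop(sprintf("IRLS did not converge in %d iterations (last penalized deviance %.6g)",
                 max_iter, dev_old))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 deviance = dev_old, converged = converged, ridge = ridge,
                 levels = attr(yb, "levels")),
            class = "logistic_glm")
}

# first level -> 1, second -> 0
binarize_labels <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  out <- as.numeric(y == levels(y)[1])
  attr(out, "levels") <- levels(y)
  out
}

#' @export
predict.logistic_glm <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(newdata))
  p <- stats::plogis(drop(X %*% object$coefficients))
  if (type == "response") return(p)
  ifelse(p >= 0.5, object$levels[1], object$levels[2])
}

#' Classification accuracy of a fitted logistic model
#'
#' @param model A [fit_logistic_glm()] fit.
#' @param x Feature matrix.
#' @param y True labels.
#' @return Fraction of correct class predictions, in `[0, 1]`.
#' @export
glm_accuracy <- function(model, x, y) {
  pred <- predict(model, x, type = "class")
  mean(pred == as.character(as.factor(y)))
}

#' @export
print.logistic_glm <- function(x, ...) {
  cat(sprintf("<logistic_glm> %d coefficient(s), ridge %g, deviance %.4g\n",
              length(x$coefficients), x$ridge, x$deviance))
  invisible(x)
}

#' @method tidy logistic_glm
#' @export
tidy.logistic_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance logistic_glm
#' @export
glance.logistic_glm <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, ridge = x$ridge,
                 converged = x$converged)
}
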