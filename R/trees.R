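# Minimal regression-tree machinery used by the pluggable regressors:
# gradient-boosted stumps for QC drift correction and bagged CART trees for
# the iterative missing-value imputer. Squared-error splits throughout, so
# fits are equivariant to rescaling of the response.

# best single split of y on predictor x; returns NULL if no admissible split
best_split <- function(x, y, min_obs = 2L) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  if (n < 2L * min_obs) return(NULL)
  cs <- cumsum(ys); tot <- cs[n]
  nl <- seq_len(n - 1L)
  # only split between distinct x values, with min_obs on both sides
  ok <- (xs[-n] < xs[-1L]) & nl >= min_obs & (n - nl) >= min_obs
  if (!any(ok)) return(NULL)
  # SSE reduction = sumL^2/nL + sumR^2/nR - tot^2/n  (up to constant)
  gain <- cs[nl]^2 / nl + (tot - cs[nl])^2 / (n - nl) - tot^2 / n
  gain[!ok] <- -Inf
  k <- which.max(gain)
  list(split = (xs[k] + xs[k + 1L]) / 2,
       left = cs[k] / k, right = (tot - cs[k]) / (n - k),
       gain = gain[k])
}

# --- gradient-boosted stumps ------------------------------------------------

#' Fit a gradient-boosted stump regressor
#'
#' Squared-error gradient boosting with depth-one regression trees, used as
#' the default QC-trained drift model. Deliberately small: with injection
#' order and batch as the only covariates, step functions of injection
#' order already span everything the drift model needs.
#'
#' @param x Numeric covariate matrix (rows = observations).
#' @param y Numeric response.
#' @param n_rounds Number of boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param min_obs Minimum observations per leaf.
#' @return A `gbt` model for [predict.gbt()].
#' @keywords internal
gbt_fit <- function(x, y, n_rounds = 50L, learning_rate = 0.1, min_obs = 2L) {
  x <- as.matrix(x)
  init <- mean(y)
  pred <- rep(init, length(y))
  var_k <- integer(n_rounds); split_k <- left_k <- right_k <- numeric(n_rounds)
  used <- 0L
  for (k in seq_len(n_rounds)) {
    r <- y - pred
    best <- NULL; best_var <- 0L
    for (j in seq_len(ncol(x))) {
      s <- best_split(x[, j], r, min_obs)
      if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
        best <- s; best_var <- j
      }
    }
    if (is.null(best) || best$gain <= 0) break
    used <- k
    var_k[k] <- best_var; split_k[k] <- best$split
    left_k[k] <- best$left; right_k[k] <- best$right
    pred <- pred + learning_rate *
      ifelse(x[, best_var] <= best$split, best$left, best$right)
  }
  structure(list(init = init, learning_rate = learning_rate,
                 var = var_k[seq_len(used)], split = split_k[seq_len(used)],
                 left = left_k[seq_len(used)], right = right_k[seq_len(used)]),
            class = "gbt")
}

#' @export
predict.gbt <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  pred <- rep(object$init, nrow(x))
  for (k in seq_along(object$var)) {
    pred <- pred + object$learning_rate *
      ifelse(x[, object$var[k]] <= object$split[k],
             object$left[k], object$right[k])
  }
  pred
}

# --- bagged CART trees ------------------------------------------------------

rtree_grow <- function(x, y, rows, depth, max_depth, min_node, mtry) {
  if (depth >= max_depth || length(rows) < 2L * min_node ||
      stats::var(y[rows]) == 0) {
    return(list(leaf = TRUE, value = mean(y[rows])))
  }
  vars <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_var <- 0L
  for (j in vars) {
    s <- best_split(x[rows, j], y[rows], min_node)
    if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
      best <- s; best_var <- j
    }
  }
  if (is.null(best) || best$gain <= 0)
    return(list(leaf = TRUE, value = mean(y[rows])))
  go_left <- x[rows, best_var] <= best$split
  list(leaf = FALSE, var = best_var, split = best$split,
       left = rtree_grow(x, y, rows[go_left], depth + 1L, max_depth,
                         min_node, mtry),
       right = rtree_grow(x, y, rows[!go_left], depth + 1L, max_depth,
                          min_node, mtry))
}

rtree_predict <- function(node, x) {
  if (node$leaf) return(rep(node$value, nrow(x)))
  out <- numeric(nrow(x))
  go_left <- x[, node$var] <= node$split
  if (any(go_left)) out[go_left] <- rtree_predict(node$left, x[go_left, , drop = FALSE])
  if (any(!go_left)) out[!go_left] <- rtree_predict(node$right, x[!go_left, , drop = FALSE])
  out
}

#' Fit a bagged ensemble of regression trees
#'
#' Random-forest style regressor (bootstrap rows, random predictor subsets
#' at each node) behind the iterative imputer.
#'
#' @param x Predictor matrix.
#' @param y Response vector.
#' @param n_trees Ensemble size.
#' @param max_depth Maximum tree depth.
#' @param min_node Minimum observations per leaf.
#' @param mtry Predictors tried per node (default `ceiling(sqrt(ncol(x)))`).
#' @return A `bagged_trees` model for [predict.bagged_trees()].
#' @keywords internal
bagged_trees_fit <- function(x, y, n_trees = 10L, max_depth = 3L,
                             min_node = 5L, mtry = NULL) {
  x <- as.matrix(x)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(x))))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- sample.int(nrow(x), nrow(x), replace = TRUE)
    trees[[t]] <- rtree_grow(x, y, rows, 0L, max_depth, min_node, mtry)
  }
  structure(list(trees = trees), class = "bagged_trees")
}

#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  preds <- vapply(object$trees, rtree_predict, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}
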