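#' Principal component scores of a centred, unit-variance matrix
#'
#' Centring and unit-variance scaling are applied internally (the
#' convention for all projections in this pipeline), constant features are
#' dropped, and the singular value decomposition provides scores (left
#' singular vectors times singular values), loadings and per-component
#' explained variance. Explained variances sum to the number of
#' non-constant features.
#'
#' @param x Numeric matrix, samples x features.
#' @param n_components Components to keep; silently capped at
#'   `min(n - 1, p)` with a message.
#' @return A `pca_result`: `scores`, `loadings`, `explained_variance`,
#'   `prop_variance`.
#' @export
pca_scores <- function(x, n_components) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  xs <- scale(x, center = TRUE, scale = sds)
  cap <- min(nrow(x) - 1, ncol(x))
  if (n_components > cap) {
    message("n_components capped at ", cap)
    n_components <- cap
  }
  sv <- svd(xs, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  ev <- sv$d^2 / (nrow(x) - 1)
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance = ev[seq_len(n_components)],
                 all_variances = ev,
                 prop_variance = ev[seq_len(n_components)] / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d components; var explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$prop_variance), collapse = ", ")))
  invisible(x)
}

#' Agglomerative clustering by the Ward.D2 convention
#'
#' Pairwise distances (Manhattan by default, the pipeline's convention for
#' sample dendrograms) are squared and agglomerated with the Lance-Williams
#' recurrence using Ward coefficients; merge heights are reported back on
#' the original scale (square root). This reproduces the widely used
#' "Ward.D2" linkage applied verbatim to non-Euclidean dissimilarities.
#'
#' @param points Numeric matrix, n x d, one row per object.
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return An `hca_dendrogram`: `merge` (hclust convention: negative =
#'   singleton), `height` (non-decreasing), `order`, `labels`.
#' @export
hca_ward2 <- function(points, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least two points")
  labels <- rownames(points) %||% as.character(seq_len(n))
  D2 <- as.matrix(stats::dist(points, method = metric))^2
  diag(D2) <- Inf
  sizes <- rep(1L, n)
  id <- -(seq_len(n))          # hclust encoding of active clusters
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (s in seq_len(n - 1)) {
    live <- which(active)
    sub <- D2[live, live, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- live[min(k)]; j <- live[max(k)]
    height[s] <- sqrt(D2[i, j])
    pair <- sort(c(id[i], id[j]))
    merge[s, ] <- pair
    # Lance-Williams update (Ward): new cluster stored at slot i
    ni <- sizes[i]; nj <- sizes[j]
    others <- live[!live %in% c(i, j)]
    if (length(others) > 0) {
      nk <- sizes[others]
      upd <- ((ni + nk) * D2[i, others] + (nj + nk) * D2[j, others] -
                nk * D2[i, j]) / (ni + nj + nk)
      D2[i, others] <- upd
      D2[others, i] <- upd
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- s
    members[[i]] <- c(members[[i]], members[[j]])
  }
  ord <- dendrogram_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, metric = metric, method = "ward.D2"),
            class = "hca_dendrogram")
}

# leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.hca_dendrogram <- function(x, ...) {
  cat(sprintf("<hca_dendrogram> %d leaves, %s linkage on %s distance\n",
              length(x$labels), x$method, x$metric))
  invisible(x)
}

#' @export
as.hclust.hca_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$metric),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges and labels the resulting connected
#' components 1..k in order of first appearance (leaf order of the input).
#'
#' @param dend An [hca_ward2()] dendrogram.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels named by leaf labels.
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_rep <- integer(n - 1)       # representative leaf of each merge
  n_keep <- n - k
  for (s in seq_len(n_keep)) {
    a <- dend$merge[s, 1]; b <- dend$merge[s, 2]
    ra <- find(if (a < 0) -a else cluster_rep[a])
    rb <- find(if (b < 0) -b else cluster_rep[b])
    parent[rb] <- ra
    cluster_rep[s] <- ra
  }
  if (n_keep < n - 1) {
    for (s in seq((n_keep + 1), n - 1)) {
      a <- dend$merge[s, 1]
      cluster_rep[s] <- find(if (a < 0) -a else cluster_rep[a])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labs <- match(roots, unique(roots[dend$order]))
  stats::setNames(labs, dend$labels)
}
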