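#' Metabolome-based sample labeling (semi-supervised step)
#'
#' Projects the analysis-ready (autoscaled, technical-replicate-averaged)
#' table onto its first `n_pcs` principal components, clusters the score
#' coordinates by Ward.D2 linkage on Manhattan distances, and cuts the
#' dendrogram at `k` groups. The resulting labels replace uncertain prior
#' classifications (genetic, geographic) as the class variable for marker
#' selection.
#'
#' Cluster numbering is deterministic: when the corresponding unscaled
#' table is supplied, cluster 1 is the cluster whose samples have the
#' higher grand mean log2 intensity (marker compounds in the emulated study
#' are more abundant in group 1); ties, or a missing `raw_table`, fall back
#' to calling the smaller cluster 1.
#'
#' @param table Autoscaled [peak_table] of study samples.
#' @param n_pcs Principal components to cluster on (default 10; capped at
#'   what the sample count supports, with a message).
#' @param k Number of clusters (default 2).
#' @param raw_table Optional unscaled counterpart of `table` used for the
#'   cluster-numbering rule.
#' @return A `cluster_assignment`: per-sample tibble (`sample_id`,
#'   `cultivar`, `bio_rep`, `label`), per-cultivar majority `consensus`,
#'   the dendrogram, and `n_pcs_used`.
#' @export
assign_metabolome_labels <- function(table, n_pcs = 10, k = 2,
                                     raw_table = NULL) {
  validate_peak_table(table)
  if (!table$scaled) stop("assign_metabolome_labels expects an autoscaled table")
  n <- n_samples(table)
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
  pca <- pca_scores(table$intensities, n_pcs)
  dend <- hca_ward2(pca$scores, metric = "manhattan")
  raw_labels <- cut_dendrogram(dend, k)
  label <- renumber_clusters(raw_labels, table, raw_table)
  samples <- tibble::tibble(sample_id = table$samples$sample_id,
                            cultivar = table$samples$cultivar,
                            bio_rep = table$samples$bio_rep,
                            label = label)
  consensus <- samples |>
    dplyr::filter(!is.na(.data$cultivar)) |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::summarise(label = majority_label(.data$label), .groups = "drop")
  structure(list(samples = samples, consensus = consensus,
                 dendrogram = dend, pca = pca,
                 n_pcs_used = ncol(pca$scores)),
            class = "cluster_assignment")
}

majority_label <- function(x) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1)
    stop("tied majority among replicates (labels ", paste(top, collapse = "/"), ")")
  as.integer(top)
}

# deterministic numbering: higher grand-mean log2 raw intensity -> 1,
# fallback smaller cluster -> 1
renumber_clusters <- function(raw_labels, table, raw_table) {
  ids <- sort(unique(raw_labels))
  key <- NULL
  if (!is.null(raw_table)) {
    idx <- match(table$samples$sample_id, raw_table$samples$sample_id)
    if (!anyNA(idx)) {
      gm <- vapply(ids, function(g) {
        mean(log2(pmax(raw_table$intensities[idx[raw_labels == g], , drop = FALSE],
                       .Machine$double.eps)))
      }, numeric(1))
      if (length(unique(gm)) == length(gm)) key <- -gm   # higher mean first
    }
  }
  if (is.null(key)) {
    sizes <- vapply(ids, function(g) sum(raw_labels == g), numeric(1))
    key <- rank(sizes, ties.method = "first")            # smaller first
  }
  new_ids <- ids[order(key)]
  match(raw_labels, new_ids)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d samples in %d clusters on %d PCs\n",
              nrow(x$samples), length(unique(x$samples$label)), x$n_pcs_used))
  print(table(cluster = x$samples$label))
  invisible(x)
}

#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) x$samples

#' Agreement between two labelings
#'
#' Adjusted Rand index plus the cross-tabulation. The ARI is 1 iff the two
#' partitions are identical (up to renaming of labels) and has expectation
#' 0 for independent random labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return A list: `ari`, `table` (cross-tabulation).
#' @export
compare_labelings <- function(a, b) {
  if (length(a) != length(b))
    stop("labelings differ in length (", length(a), " vs ", length(b), ")")
  tab <- table(a, b)
  list(ari = adjusted_rand_index(tab), table = tab)
}

adjusted_rand_index <- function(tab) {
  choose2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
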