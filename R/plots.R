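#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of a PCA projection
#'
#' @param object A [pca_scores()] result.
#' @param colour Optional vector (one value per sample) mapped to colour,
#'   e.g. sample roles or cluster labels.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, colour = NULL, components = c(1, 2), ...) {
  df <- tibble::tibble(
    x = object$scores[, components[1]],
    y = object$scores[, components[2]],
    label = rownames(object$scores) %||% as.character(seq_len(nrow(object$scores))))
  if (!is.null(colour)) df$colour <- colour
  pv <- 100 * object$prop_variance[components]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", components[1], pv[1]),
                  y = sprintf("PC%d (%.1f%%)", components[2], pv[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Dendrogram plot
#'
#' @param object An [hca_ward2()] dendrogram.
#' @param label_colour Optional vector of per-leaf values mapped to the
#'   label colour (e.g. cluster or group membership).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hca_dendrogram
#' @export
autoplot.hca_dendrogram <- function(object, label_colour = NULL, ...) {
  n <- length(object$labels)
  xpos <- numeric(n)
  xpos[object$order] <- seq_len(n)
  node_x <- node_y <- numeric(n - 1)
  segs <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    child <- function(v) {
      if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
    }
    a <- child(object$merge[s, 1]); b <- child(object$merge[s, 2])
    h <- object$height[s]
    node_x[s] <- (a[1] + b[1]) / 2; node_y[s] <- h
    segs[[s]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h), yend = c(h, h, b[2]))
  }
  leaves <- tibble::tibble(x = xpos, label = object$labels,
                           colour = if (is.null(label_colour)) "leaf"
                                    else as.character(label_colour))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(segs),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label,
                                    colour = .data$colour),
                       angle = 90, hjust = 1.05, size = 2.5,
                       show.legend = !is.null(label_colour)) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = sprintf("%s height (%s)", object$method,
                                        object$metric), colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-feature QC RSD before/after drift correction
#'
#' @param report The `report` tibble of [qc_drift_correct()].
#' @param threshold_pct Reference line, percent.
#' @return A ggplot.
#' @export
plot_rsd_report <- function(report, threshold_pct = 30) {
  long <- tidyr::pivot_longer(report, c("rsd_before", "rsd_after"),
                              names_to = "stage", values_to = "rsd")
  long$stage <- factor(long$stage, levels = c("rsd_before", "rsd_after"),
                       labels = c("before correction", "after correction"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rsd, fill = .data$stage)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.55) +
    ggplot2::geom_vline(xintercept = threshold_pct, linetype = 2) +
    ggplot2::labs(x = "QC RSD (%)", y = "features", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Outer-fold summary of a nested selection run
#'
#' Selected-set size and held-out GLM accuracy per outer fold.
#'
#' @param object A [run_nested_selection()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tibble::tibble(
    fold = factor(seq_along(object$outer_sets)),
    set_size = lengths(object$outer_sets),
    accuracy = object$outer_accuracies)
  long <- tidyr::pivot_longer(df, c("set_size", "accuracy"),
                              names_to = "what", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "outer fold", y = NULL) +
    ggplot2::theme_minimal()
}
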