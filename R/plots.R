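#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_line
#'   geom_point geom_vline geom_histogram scale_fill_gradient2 labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot a clustered heatmap
#'
#' Tile plot of the z-scored, dendrogram-ordered matrix produced by
#' [cluster_heatmap()].
#'
#' @param object A `cluster_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(object$values, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "z") |>
    dplyr::mutate(row = factor(.data$row, levels = rev(rownames(object$values))),
                  col = factor(.data$col, levels = colnames(object$values)))
  ggplot(df, aes(.data$col, .data$row, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot the marker selection result
#'
#' Importance ranking with the cumulative-accuracy curve and the selected
#' panel size.
#'
#' @param object A `marker_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.marker_panel <- function(object, ...) {
  ggplot(object$curve, aes(.data$k, .data$cumulative_accuracy)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = object$selected_k, linetype = "dashed") +
    labs(x = "panel size (top-k probes)", y = "10-fold CV accuracy",
         title = sprintf("plateau at k = %d", object$selected_k)) +
    theme_minimal()
}

#' Plot a permutation-null summary
#'
#' Histogram of the per-shuffle significant-gene counts with the observed
#' count marked.
#'
#' @param object A [permutation_null()] result (one-row tibble with the
#'   `null_counts` attribute).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_permutation_null <- function(object, ...) {
  counts <- attr(object, "null_counts")
  ggplot(tibble::tibble(count = counts), aes(.data$count)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed_significant_genes,
               colour = "#b2182b", linewidth = 1) +
    labs(x = "significant genes per shuffle",
         y = "shuffles",
         title = sprintf("observed = %d, null mean = %.3f (SD %.3f)",
                         object$observed_significant_genes,
                         object$null_mean, object$null_sd)) +
    theme_minimal()
}

#' Plot per-class classifier performance
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot of per-class AUC with confidence intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.classifier_report <- function(object, ...) {
  ggplot(object$per_class,
         aes(.data$class_label, .data$auc)) +
    geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(aes(ymin = .data$auc_lo, ymax = .data$auc_hi),
                           width = 0.2) +
    labs(x = NULL, y = "one-vs-rest AUC") +
    theme_minimal()
}
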