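#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an origin model
#'
#' One row per class with the chosen hyperparameters, OOB score and
#' cross-validated metrics.
#'
#' @param x An `origin_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.origin_model <- function(x, ...) {
  cv <- x$cv |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(cv_accuracy = mean(.data$accuracy),
                     cv_auc = mean(.data$auc), .groups = "drop")
  dplyr::left_join(x$chosen, cv, by = "class_label")
}

#' @rdname tidy.origin_model
#' @exportS3Method generics::glance
glance.origin_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    panel_size = length(x$panel),
    mean_cv_accuracy = mean(x$cv$accuracy),
    mean_cv_auc = mean(x$cv$auc),
    seed = x$seed
  )
}

#' Tidy a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return Per-class metric tibble (accuracy and AUC with 95% CI).
#' @exportS3Method generics::tidy
tidy.classifier_report <- function(x, ...) x$per_class

#' @rdname tidy.classifier_report
#' @exportS3Method generics::glance
glance.classifier_report <- function(x, ...) x$overall

#' Tidy a marker panel
#'
#' @param x A `marker_panel`.
#' @param ... Unused.
#' @return The importance ranking joined with the accuracy curve.
#' @exportS3Method generics::tidy
tidy.marker_panel <- function(x, ...) {
  dplyr::left_join(x$ranking, x$curve, by = c(rank = "k")) |>
    dplyr::mutate(selected = .data$rank <= x$selected_k)
}

#' @rdname tidy.marker_panel
#' @exportS3Method generics::glance
glance.marker_panel <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(unique(x$candidates$probe_id)),
    n_passing = length(unique(x$candidates$probe_id[x$candidates$passes])),
    selected_k = x$selected_k,
    plateau_accuracy = x$curve$cumulative_accuracy[x$selected_k]
  )
}
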