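#' Bar profile of predictor importance
#'
#' Horizontal bar chart of the relative importance (0-1) of each ROI in
#' separating the clusters, most important at the top.
#'
#' @param importance An `als_importance` tibble from [predictor_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  df <- tibble::as_tibble(importance)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$roi, .data$importance))) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "relative predictor importance", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname plot_importance
#' @param object An `als_importance` tibble.
#' @param ... Unused.
#' @export
autoplot.als_importance <- function(object, ...) plot_importance(object)

#' Pairwise scatter of subjects along the most discriminating ROIs
#'
#' Plots cluster membership along the integrity gradients of the chosen
#' ROIs (by default the fit's three most important, or the first three
#' score columns if no importance table is given), as the pairwise panels
#' of the corresponding 3-D score cloud.
#'
#' @param scores An `als_scores` tibble.
#' @param fit A `twostep_fit`.
#' @param rois Character vector of ROI columns to plot (2 or 3).
#' @param importance Optional `als_importance` used to pick the top ROIs.
#' @return A ggplot object (facetted pairwise panels).
#' @export
plot_score_scatter <- function(scores, fit, rois = NULL, importance = NULL) {
  if (is.null(rois)) {
    rois <- if (!is.null(importance)) utils::head(importance$roi, 3) else
      utils::head(setdiff(names(scores), "subject_id"), 3)
  }
  stopifnot(length(rois) >= 2, all(rois %in% names(scores)))
  df <- dplyr::inner_join(tibble::as_tibble(scores)[c("subject_id", rois)],
                          fit$assignments, by = "subject_id")
  pairs <- utils::combn(rois, 2, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(panel = paste(p[1], "vs", p[2]),
                   x = df[[p[1]]], y = df[[p[2]]],
                   cluster = factor(df$cluster))
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "composite integrity score", y = "composite integrity score",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' BIC trace of a two-step fit
#'
#' @param object A `twostep_fit`.
#' @param k_max Largest cluster count to display.
#' @param ... Unused.
#' @return A ggplot object with the selected k marked.
#' @export
autoplot.twostep_fit <- function(object, k_max = 15, ...) {
  df <- dplyr::filter(object$bic, .data$k <= k_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters", y = "BIC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
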