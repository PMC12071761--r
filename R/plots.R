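#' Plot spectra colored by class
#'
#' @param object A [spectra_set()].
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot: absorbance vs wavenumber, one line per sample.
#' @method autoplot spectra_set
#' @export
autoplot.spectra_set <- function(object, alpha = 0.4, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                                   group = .data$sample_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' Scatter plot of discriminant scores
#'
#' @param scores A tibble from [project_scores()].
#' @param comps Two component column names to plot.
#' @return A ggplot of the projected samples colored by class.
#' @export
plot_scores <- function(scores, comps = c("comp_1", "comp_2")) {
  stopifnot(all(comps %in% names(scores)), length(comps) == 2)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[comps[1]]],
                                       y = .data[[comps[2]]],
                                       colour = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(colour = "Class") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a metrics report
#'
#' @param object A `metrics_report` from [run_combo_cv()].
#' @param ... Unused.
#' @return A ggplot tile map of pooled test-fold counts.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- confusion_tbl(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = object$combo_label, x = "Predicted", y = "True") +
    ggplot2::theme_minimal()
}

#' Accuracy bars across a pipeline grid
#'
#' @param grid A tibble from [grid_report()].
#' @return A ggplot: mean CV accuracy per combination, faceted by classifier.
#' @export
plot_grid_accuracy <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$preprocess, y = .data$mean_accuracy,
                               fill = .data$extractor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "Preprocessing", y = "Mean CV accuracy",
                  fill = "Extractor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
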