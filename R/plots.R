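# ggplot2 display methods for the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cross-section plot of a CAP slice
#'
#' Scatter of the slice points colored by region-growing cluster, the view
#' used to eyeball whether radius/k/area-threshold settings produce sensible
#' canopy blobs.
#'
#' @param slice Slice tibble from [take_slice()].
#' @param config Settings from [feature_config()].
#' @return A ggplot object.
#' @export
plot_cap_slice <- function(slice, config = feature_config()) {
  if (nrow(slice) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty slice") +
             ggplot2::theme_void())
  }
  slice$cluster <- factor(region_grow_clusters(slice,
                                               radius = config$cap_radius,
                                               k = config$cap_k))
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = "CAP slice clusters") +
    ggplot2::theme_minimal()
}

#' @method autoplot lai_feature_weights
#' @export
autoplot.lai_feature_weights <- function(object, ...) {
  object$feature <- stats::reorder(object$feature, object$weight)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$feature,
                                       y = .data$weight)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = expression(1 - R[new]^2 / R[original]^2), x = NULL,
                  title = sprintf("Leave-one-out feature weights (%s)",
                                  attr(object, "family"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of the absolute feature correlation matrix
#'
#' @param mat Matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(mat) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(mat, rownames = "feature_a"),
    -"feature_a", names_to = "feature_b", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_a, y = .data$feature_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#d7301f",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "|r|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Observed-vs-predicted scatter for a fitted model
#'
#' @param model Fitted `lai_smlr`/`lai_plsr`/`lai_svr` object.
#' @param test Held-out dataset.
#' @return A ggplot object with the 1:1 line and test R^2/RMSE annotated.
#' @export
plot_predictions <- function(model, test) {
  tab <- predictions_table(model, test)
  met <- evaluate_model(model, test)
  lim <- range(c(tab$y_true, tab$y_pred))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "reference effective LAI",
                  y = "predicted effective LAI",
                  title = sprintf("%s: R² = %.2f, RMSE = %.2f",
                                  met$family, met$r2, met$rmse)) +
    ggplot2::theme_minimal()
}
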