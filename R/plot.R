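#' Heatmap of a match surface
#'
#' Renders the grid-search match counts (or exact match probabilities)
#' over the expert-bias x congruence-bias plane, lighter cells marking
#' parameter combinations whose simulations reproduce the observed
#' counts more often. When the primacy axis varies, the surface is
#' faceted by primacy-bias value.
#'
#' @param object A `match_grid` from [run_grid()] or an `exact_moments`
#'   object from [exact_weighted_moments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_grid
#' @export
autoplot.match_grid <- function(object, ...) {
  match_surface_plot(tidy(object), "matches", "matches")
}

#' @rdname autoplot.match_grid
#' @method autoplot exact_moments
#' @export
autoplot.exact_moments <- function(object, ...) {
  match_surface_plot(object$weights, "match_probability", "match\nprobability")
}

match_surface_plot <- function(df, fill, fill_label) {
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$expert_bias, y = .data$congruent_bias,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
      name = fill_label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "expert bias", y = "congruence bias") +
    ggplot2::theme_minimal()
  if (length(unique(df$primacy_bias)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$primacy_bias))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
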