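#' Plot a run-length distribution on log-log scales
#'
#' @param object A [run_distribution()].
#' @param ... Unused.
#' @return A ggplot of the complementary cumulative distribution P(X >= x)
#'   against run length, both log-scaled.
#' @export
autoplot.run_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$ccdf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "run length x", y = "P(X ≥ x)",
                  title = "Cumulative run distribution") +
    ggplot2::theme_minimal()
}

#' Plot a two-attribute preference vector in attribute space
#'
#' @param object A [preference_vector()] over exactly two attributes.
#' @param ... Unused.
#' @return A ggplot showing the preference vector as an arrow from the origin
#'   of the (range-centred) attribute plane.
#' @export
autoplot.preference_vector <- function(object, ...) {
  if (nrow(object) != 2) {
    stop_attnrl("the attribute-space plot needs exactly 2 attributes", "attnrl_invalid_input")
  }
  df <- tibble::tibble(x = object$component[1], y = object$component[2])
  lim <- max(df$x, df$y, 0.1) * 1.15
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                          arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"))) +
    ggplot2::coord_equal(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(x = object$attribute[1], y = object$attribute[2],
                  title = "Preference vector") +
    ggplot2::theme_minimal()
}

#' Bias-persistence plane
#'
#' Scatter of subjects (or conditions) in the bias-index / persistence-index
#' plane, the standard summary of how exploitation and perseveration trade
#' off across choice contexts.
#'
#' @param data A data frame with columns `b_index`, `p_index` and a grouping
#'   column.
#' @param group Name of the grouping column (default `"condition"`).
#' @return A ggplot.
#' @export
plot_bp_plane <- function(data, group = "condition") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$b_index, y = .data$p_index,
                                     colour = factor(.data[[group]]))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "B-index (preference bias)", y = "P-index (persistence)",
                  colour = group) +
    ggplot2::theme_minimal()
}
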