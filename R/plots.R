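#' Gamma-plane scatter of stochastic signatures
#'
#' Shape on the x axis, scale on the y axis (log-log by default): the
#' Exponential range sits at shape = 1, the symmetric Gaussian-like range to
#' the right.
#'
#' @param signatures Signature tibble (e.g. from [gamma_signatures()]).
#' @param colour Optional column name mapped to colour.
#' @param log Use log-log axes.
#' @return A ggplot object.
#' @export
plot_gamma_plane <- function(signatures, colour = NULL, log = TRUE) {
  p <- ggplot2::ggplot(signatures,
                       ggplot2::aes(x = .data$shape, y = .data$scale)) +
    ggplot2::geom_point(size = 2, ggplot2::aes(
      colour = if (is.null(colour)) NULL else .data[[colour]])) +
    ggplot2::labs(x = "shape a", y = "scale b (noise-to-signal)",
                  colour = colour, title = "Gamma plane") +
    ggplot2::theme_minimal()
  if (all(c("ci_shape_low", "ci_shape_high") %in% names(signatures)))
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_shape_low, xmax = .data$ci_shape_high),
      height = 0, alpha = 0.4)
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.signature_trajectory <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shape, y = .data$scale)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(6, "pt")),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$block), size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "shape a", y = "scale b",
                  title = "Stochastic signature trajectory") +
    ggplot2::theme_minimal()
}

#' Rule scatter with fitted lines
#'
#' @param scatter A [build_rule_scatter()] result.
#' @param fit Optional [fit_rule()] result drawn as line(s).
#' @return A ggplot object.
#' @export
plot_rule_scatter <- function(scatter, fit = NULL) {
  has_lv <- "speed_level" %in% names(scatter)
  p <- ggplot2::ggplot(as_tibble(scatter),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, ggplot2::aes(
      colour = if (has_lv) .data$speed_level else NULL)) +
    ggplot2::labs(x = "ln amax(t)", y = "ln(vmax(t+1) + nu vmax(t))",
                  colour = "speed level",
                  title = "First-order stochastic rule") +
    ggplot2::theme_minimal()
  if (!is.null(fit))
    p <- p + ggplot2::geom_abline(
      data = fit$coef, ggplot2::aes(slope = .data$m, intercept = .data$b),
      linetype = 2)
  p
}

#' @export
autoplot.linearity_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frac, y = .data$deviation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized time", y = "deviation from chord (m)",
                  title = "Trajectory linearity profile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
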