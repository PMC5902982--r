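#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot regional ageing-rate trajectories
#'
#' @param object A `bstm_panel`.
#' @param ... Unused.
#' @return A ggplot: one line of ageing rate per region over the years.
#' @export
autoplot.bstm_panel <- function(object, ...) {
  rates <- ageing_rates(object)
  ggplot2::ggplot(rates, ggplot2::aes(.data$year, .data$rate,
                                      group = .data$region)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "year", y = "ageing rate",
                  title = "Regional ageing rates") +
    ggplot2::theme_minimal()
}

#' Plot a national forecast
#'
#' @param object A `bstm_forecast` from [predict_rate()].
#' @param ... Unused.
#' @return A ggplot of the forecast median and 95% credible band.
#' @export
autoplot.bstm_forecast <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$year, .data$rate_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate_lo,
                                      ymax = .data$rate_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "year", y = "forecast ageing rate",
                  title = "National ageing-rate forecast (95% CI)") +
    ggplot2::theme_minimal()
}

#' Quadrant plot of local trend classifications
#'
#' Scatter of the posterior median local linear trend (`b1`, growth relative
#' to the overall trend) against the local quadratic term (`b2`,
#' acceleration), coloured by the four-quadrant label.
#'
#' @param trends A tibble from [classify_trends()].
#' @return A ggplot.
#' @export
plot_trend_quadrants <- function(trends) {
  ggplot2::ggplot(trends, ggplot2::aes(.data$b1_median, .data$b2_median,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "local linear trend b1 (median)",
                  y = "local acceleration b2 (median)",
                  colour = "trend class") +
    ggplot2::theme_minimal()
}

#' Caterpillar plot of the common spatial pattern
#'
#' Posterior medians and 95% intervals of `exp(s_i)`, each region's ageing
#' level as a multiple of the overall level; the reference line at 1 is the
#' overall level `exp(alpha)`.
#'
#' @param srm A tibble from [spatial_relative_magnitude()].
#' @return A ggplot.
#' @export
plot_spatial_pattern <- function(srm) {
  srm <- dplyr::arrange(srm, .data$exp_s_median)
  srm$region <- factor(srm$region, levels = srm$region)
  ggplot2::ggplot(srm, ggplot2::aes(.data$exp_s_median, .data$region)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$exp_s_lo,
                                         xmax = .data$exp_s_hi),
                            height = 0, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "exp(s_i): ageing level relative to overall",
                  y = NULL) +
    ggplot2::theme_minimal()
}
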