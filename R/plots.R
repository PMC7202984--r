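# ggplot2 visualisations of each result type.

#' @method autoplot circ_series
#' @export
autoplot.circ_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = attr(object, "name") %||% "value")
}

#' @method autoplot circ_avgspec
#' @export
autoplot.circ_avgspec <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$period, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "period (s)", y = "average wavelet power",
                  title = attr(object, "series_name"))
}

#' @method autoplot circ_cwt
#' @export
autoplot.circ_cwt <- function(object, ...) {
  df <- tidy(object)
  coi <- tibble(time = object$times, period = object$coi)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::geom_line(data = coi, colour = "white", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "period (s)",
                  title = object$series_name)
}

#' @method autoplot circ_xwt
#' @export
autoplot.circ_xwt <- function(object, ...) {
  df <- tidy(object)
  coi <- tibble(time = object$times, period = object$coi)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$cross_power)) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$significant)),
                          breaks = 0.5, colour = "white") +
    ggplot2::geom_line(data = coi, colour = "white", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "period (s)",
                  title = paste(object$names, collapse = " x "))
}

#' @method autoplot circ_ccf
#' @export
autoplot.circ_ccf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "lag_at_max"),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "lag (s)", y = "cross-correlation")
}

#' @method autoplot circ_loess
#' @export
autoplot.circ_loess <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = attr(object, "series_name") %||% "value")
}

#' Average-spectrum panel over situations and variables
#'
#' One line per variable, one facet per situation — the package's equivalent
#' of reading a patient's circulatory frequency distribution across the
#' perioperative course.
#'
#' @param report A `circ_report`.
#' @return A ggplot object.
#' @export
plot_spectra <- function(report) {
  df <- tidy(report)
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$power,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~situation) +
    ggplot2::labs(x = "period (s)", y = "average wavelet power")
}
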