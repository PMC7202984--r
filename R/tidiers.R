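# broom-style tidiers for the result objects.

#' @describeIn morlet_cwt Long tibble of `(time, period, power, in_coi)`.
#' @param x A `circ_cwt`.
#' @param ... Unused.
#' @method tidy circ_cwt
#' @export
tidy.circ_cwt <- function(x, ...) {
  tibble(
    time = rep(x$times, each = length(x$periods)),
    period = rep(x$periods, times = length(x$times)),
    power = as.vector(x$power),
    in_coi = as.vector(outer(x$periods, x$coi, `>`))
  )
}

#' @method glance circ_cwt
#' @export
glance.circ_cwt <- function(x, ...) {
  tibble(series = x$series_name, n_times = length(x$times),
         n_periods = length(x$periods),
         period_min = min(x$periods), period_max = max(x$periods))
}

#' @method tidy circ_avgspec
#' @export
tidy.circ_avgspec <- function(x, ...) {
  tibble(period = x$period, power = x$power)
}

#' @method glance circ_avgspec
#' @export
glance.circ_avgspec <- function(x, ...) {
  i <- which.max(x$power)
  tibble(series = attr(x, "series_name") %||% NA_character_,
         peak_period = x$period[i], peak_power = x$power[i])
}

#' @describeIn cross_wavelet Long tibble of
#'   `(time, period, cross_power, phase, significant, in_coi)`.
#' @param x A `circ_xwt`.
#' @param ... Unused.
#' @method tidy circ_xwt
#' @export
tidy.circ_xwt <- function(x, ...) {
  tibble(
    time = rep(x$times, each = length(x$periods)),
    period = rep(x$periods, times = length(x$times)),
    cross_power = as.vector(x$cross_power),
    phase = as.vector(x$phase),
    significant = as.vector(x$significant),
    in_coi = as.vector(outer(x$periods, x$coi, `>`))
  )
}

#' @method glance circ_xwt
#' @export
glance.circ_xwt <- function(x, ...) {
  tibble(pair = paste(x$names, collapse = "-"), alpha = x$alpha,
         prop_significant = mean(x$significant))
}

#' @method tidy circ_ccf
#' @export
tidy.circ_ccf <- function(x, ...) {
  tibble(lag = x$lag, correlation = x$correlation)
}

#' @describeIn cross_correlation One-row summary with `ccf_max` and
#'   `lag_at_max`.
#' @param x A `circ_ccf`.
#' @param ... Unused.
#' @method glance circ_ccf
#' @export
glance.circ_ccf <- function(x, ...) {
  nm <- attr(x, "names_ab")
  tibble(a = nm[1], b = nm[2],
         ccf_max = attr(x, "ccf_max"), lag_at_max = attr(x, "lag_at_max"))
}

#' @describeIn loess_decompose Long tibble of `(time, component, value)`.
#' @param x A `circ_loess`.
#' @param ... Unused.
#' @method tidy circ_loess
#' @export
tidy.circ_loess <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time",
                      names_to = "component", values_to = "value")
}

#' @method glance circ_loess
#' @export
glance.circ_loess <- function(x, ...) {
  sp <- attr(x, "spans")
  tibble(span1 = sp[1], span2 = sp[2], span3 = sp[3],
         residual_sd = sd(x$residual))
}

#' @describeIn run_pipeline Long tibble of all average spectra:
#'   `(situation, variable, period, power)`.
#' @param x A `circ_report`.
#' @param ... Unused.
#' @method tidy circ_report
#' @export
tidy.circ_report <- function(x, ...) {
  purrr::map_dfr(x$situations, function(s) {
    if (isTRUE(s$failed)) return(NULL)
    purrr::map_dfr(names(s$avg_spectra), function(v) {
      dplyr::mutate(tidy(s$avg_spectra[[v]]),
                    situation = s$label, variable = v, .before = 1)
    })
  })
}

#' @method glance circ_report
#' @export
glance.circ_report <- function(x, ...) {
  purrr::map_dfr(x$situations, function(s) {
    if (isTRUE(s$failed)) {
      return(tibble(situation = s$label, failed = TRUE, n_peaks = NA_integer_,
                    beats_detected = NA_integer_, outliers_removed = NA_integer_))
    }
    tibble(situation = s$label, failed = FALSE, n_peaks = nrow(s$peaks),
           beats_detected = s$log$beats_detected[s$log$variable == "iAmp"],
           outliers_removed = sum(s$log$outliers_removed))
  })
}
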