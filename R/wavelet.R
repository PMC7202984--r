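# Morlet continuous wavelet transform, average wavelet power spectra and
# bivariate cross-wavelet spectra with surrogate significance testing.
#
# The transform follows the standard FFT implementation: the signal is
# zero-padded to the next power of two, multiplied in the frequency domain
# by the scaled Morlet window (energy-normalised per scale), and transformed
# back; the cone of influence marks cells within one wavelet e-folding time
# of an edge.

#' Configuration for the wavelet analyses
#'
#' @param omega0 Morlet central frequency (dimensionless, default 6 — the
#'   conventional choice balancing time and frequency resolution).
#' @param period_min,period_max Bounds of the period grid, s (defaults 10 and
#'   1,024: the band of slow circulatory oscillations).
#' @param voices_per_octave Scales per octave on the log2 period grid
#'   (default 12).
#' @param alpha Significance level for cross-wavelet masks (default 0.05).
#' @param n_surrogates Surrogate pairs used to build the significance null
#'   (default 100).
#' @param null `"white"` (default) or `"red"`: white-noise surrogates, or
#'   AR(1) surrogates with lag-1 autocorrelation estimated from the data.
#' @param exclude_coi Should time-averages skip cells inside the cone of
#'   influence (default `TRUE`)?
#' @return A list of class `"circ_wavelet_config"`.
#' @export
wavelet_config <- function(omega0 = 6, period_min = 10, period_max = 1024,
                           voices_per_octave = 12, alpha = 0.05,
                           n_surrogates = 100,
                           null = c("white", "red"),
                           exclude_coi = TRUE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (period_min <= 0 || period_max <= period_min) {
    abort("need 0 < period_min < period_max.")
  }
  structure(list(
    omega0 = omega0, period_min = period_min, period_max = period_max,
    voices_per_octave = voices_per_octave, alpha = alpha,
    n_surrogates = n_surrogates, null = match.arg(null),
    exclude_coi = exclude_coi
  ), class = "circ_wavelet_config")
}

wavelet_periods <- function(config) {
  n_oct <- log2(config$period_max / config$period_min)
  config$period_min * 2^(seq(0, n_oct, by = 1 / config$voices_per_octave))
}

# period of a Fourier sinusoid with the same spectral peak as scale s
morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# core transform; x numeric, returns complex scales x time matrix
morlet_engine <- function(x, dt, periods, omega0) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xhat <- fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  scales <- periods / morlet_fourier_factor(omega0)
  pos <- omega > 0
  W <- matrix(0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    window <- numeric(npad)
    window[pos] <- sqrt(2 * pi * s / dt) * pi^-0.25 *
      exp(-0.5 * (s * omega[pos] - omega0)^2)
    w <- fft(xhat * window, inverse = TRUE) / npad
    W[si, ] <- w[seq_len(n)]
  }
  W
}

series_values <- function(series) {
  if (inherits(series, "circ_series") || is.data.frame(series)) {
    list(x = series$value, t = series$time,
         dt = 1 / (attr(series, "fs") %||% (1 / diff(series$time[1:2]))))
  } else {
    abort("expected a `circ_series` (tibble with time and value).")
  }
}

#' Morlet continuous wavelet transform of a uniform series
#'
#' The series is standardised (zero mean, unit variance) and convolved with
#' scaled Morlet wavelets on a log2-spaced period grid.  Power is the
#' squared coefficient magnitude; the cone of influence gives, per time
#' point, the longest period free of edge effects.
#'
#' @param series A `circ_series` (see [interpolate_to_uniform()]).
#' @param config A [wavelet_config()].
#' @param standardize Scale to unit variance before the transform (default
#'   `TRUE`; spectra of variables with different units become comparable).
#'   With `standardize = FALSE` only the mean is removed, so power scales
#'   with the squared signal amplitude.
#' @return A `circ_cwt` object: `times`, `periods`, complex `coef`
#'   (periods x times), `power`, `coi` (max reliable period per time),
#'   `series_name`, `config`.
#' @export
morlet_cwt <- function(series, config = wavelet_config(), standardize = TRUE) {
  sv <- series_values(series)
  x <- sv$x
  n <- length(x)
  if (n < 2) abort("series too short for a wavelet transform.")
  dt <- sv$dt
  periods <- wavelet_periods(config)
  if (min(periods) < 2 * dt) abort("period grid extends below the Nyquist period.")
  if (max(periods) > n * dt / 2) {
    warn("period grid exceeds half the record length; long periods sit inside the cone of influence")
  }
  s <- sd(x)
  x <- if (standardize && s > 0) (x - mean(x)) / s else x - mean(x)
  W <- morlet_engine(x, dt, periods, config$omega0)
  edge <- pmin(sv$t - sv$t[1], sv$t[n] - sv$t) + dt / 2
  coi <- morlet_fourier_factor(config$omega0) * edge / sqrt(2)
  structure(list(
    times = sv$t, periods = periods, coef = W, power = Mod(W)^2, coi = coi,
    series_name = attr(series, "name") %||% "series", config = config
  ), class = "circ_cwt")
}

#' @export
print.circ_cwt <- function(x, ...) {
  cat("<circ_cwt> ", x$series_name, ": ", length(x$periods), " periods (",
      round(min(x$periods), 1), "-", round(max(x$periods), 1), " s) x ",
      length(x$times), " times\n", sep = "")
  invisible(x)
}

#' Average wavelet power spectrum
#'
#' Per-period arithmetic mean of wavelet power over time — the summary used
#' to read a recording's frequency distribution.  With
#' `exclude_coi = TRUE` only cells outside the cone of influence enter the
#' mean; periods with no valid cell are returned as `NA`.
#'
#' @param spectrum A `circ_cwt`.
#' @param exclude_coi Override of the config default.
#' @return A `circ_avgspec`: tibble with `period` (s) and `power`.
#' @export
average_power <- function(spectrum, exclude_coi = NULL) {
  stopifnot(inherits(spectrum, "circ_cwt"))
  exclude_coi <- exclude_coi %||% spectrum$config$exclude_coi
  pw <- spectrum$power
  if (exclude_coi) {
    valid <- outer(spectrum$periods, spectrum$coi, `<=`)
    pw[!valid] <- NA_real_
  }
  avg <- rowMeans(pw, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  n_valid <- rowSums(!is.na(pw))
  structure(tibble(period = spectrum$periods, power = avg),
            series_name = spectrum$series_name, exclude_coi = exclude_coi,
            n_valid = n_valid, dt = diff(spectrum$times[1:2]),
            omega0 = spectrum$config$omega0,
            class = c("circ_avgspec", class(tibble())))
}

#' Detect distinct peaks in an average wavelet power spectrum
#'
#' A "distinct" oscillatory peak is a local maximum over the period grid
#' that is statistically incompatible with the local spectral continuum.
#' The continuum is estimated by a wide running median (robust to narrow
#' peaks); the time-averaged power at scale `s`, averaged over `n` valid
#' samples of spacing `dt`, fluctuates around the continuum approximately
#' as chi-squared with `nu = 2 * sqrt(1 + (n * dt / (gamma * s))^2)` degrees
#' of freedom (`gamma` = 2.32, the Morlet decorrelation factor), and a peak
#' must exceed the continuum times the upper `conf` quantile of that
#' distribution.
#'
#' Periods whose average pools fewer than `min_dof` degrees of freedom
#' (roughly `min_dof / 2` independent wavelet samples) are never reported:
#' over a 30-min record this excludes periods of several hundred seconds and
#' longer, where a background fluctuation or a few transient noise events
#' are indistinguishable from a genuine oscillation.
#'
#' @param avg A `circ_avgspec` from [average_power()].
#' @param conf Confidence level a maximum must reach against the continuum
#'   (default 0.99).
#' @param min_dof Minimum chi-squared degrees of freedom for a period to be
#'   eligible (default 10).
#' @param window_octaves Half-width, in octaves, of the running-median
#'   continuum window (default 1.5).
#' @return A tibble of `period`, `power`, strongest first.
#' @export
find_spectral_peaks <- function(avg, conf = 0.99, min_dof = 10,
                                window_octaves = 1.5) {
  p <- avg$power
  n <- length(p)
  if (n < 3) abort("need at least 3 grid points.")
  steps <- diff(log2(avg$period))
  half <- max(1L, round(window_octaves / median(steps)))
  continuum <- vapply(seq_len(n), function(i) {
    median(p[max(1, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
  n_valid <- attr(avg, "n_valid")
  dt <- attr(avg, "dt")
  omega0 <- attr(avg, "omega0") %||% 6
  nu <- if (is.null(n_valid) || is.null(dt)) {
    rep(Inf, n)                      # bare spectra: plain continuum excess
  } else {
    scales <- avg$period / morlet_fourier_factor(omega0)
    2 * sqrt(1 + (n_valid * dt / (2.32 * scales))^2)
  }
  thr <- continuum * ifelse(is.finite(nu), stats::qchisq(conf, nu) / nu, 1)
  ok <- function(i) !is.na(p[i])
  is_peak <- vapply(2:(n - 1), function(i) {
    ok(i) && ok(i - 1) && ok(i + 1) &&
      p[i] > p[i - 1] && p[i] >= p[i + 1] &&
      nu[i] >= min_dof && !is.na(thr[i]) && p[i] > thr[i]
  }, logical(1))
  idx <- which(is_peak) + 1
  out <- tibble(period = avg$period[idx], power = p[idx])
  dplyr::arrange(out, dplyr::desc(.data$power))
}

# surrogate generator for the significance null: standardized white noise or
# AR(1) with given lag-1 coefficient
simulate_surrogate <- function(n, rho = 0) {
  if (rho <= 0) return(rnorm(n))
  x <- as.numeric(stats::arima.sim(list(ar = rho), n))
  x / sd(x)
}

#' Significance null for cross-wavelet power
#'
#' Builds the per-period null distribution of cross-wavelet power between
#' two independent surrogate series of the same length as the data, and
#' stores its upper `1 - alpha` quantile per period.  Cells of every
#' surrogate spectrum are pooled over time (thinned for memory), so the
#' threshold reflects the marginal cell distribution, edges included.
#' Computing the null once and passing it to repeated [cross_wavelet()]
#' calls on same-length series avoids re-simulation.
#'
#' @param n Series length in samples.
#' @param dt Sampling interval, s.
#' @param config A [wavelet_config()].
#' @param rho Lag-1 autocorrelations (length 2) for the red-noise null; 0
#'   (default) gives the white-noise null.
#' @param n_surrogates Override of `config$n_surrogates`.
#' @return A `circ_cw_null` with per-period quantiles.
#' @export
cw_null <- function(n, dt, config = wavelet_config(), rho = c(0, 0),
                    n_surrogates = NULL) {
  n_surrogates <- n_surrogates %||% config$n_surrogates
  periods <- wavelet_periods(config)
  keep <- unique(round(seq(1, n, length.out = min(n, 512))))
  pool <- matrix(NA_real_, length(periods), length(keep) * n_surrogates)
  for (b in seq_len(n_surrogates)) {
    wa <- morlet_engine(simulate_surrogate(n, rho[1]), dt, periods, config$omega0)
    wb <- morlet_engine(simulate_surrogate(n, rho[2]), dt, periods, config$omega0)
    cp <- Mod(wa[, keep, drop = FALSE] * Conj(wb[, keep, drop = FALSE]))
    pool[, ((b - 1) * length(keep) + 1):(b * length(keep))] <- cp
  }
  q <- apply(pool, 1, quantile, probs = 1 - config$alpha, names = FALSE)
  structure(list(periods = periods, quantile = q, alpha = config$alpha,
                 n = n, dt = dt, n_surrogates = n_surrogates, rho = rho),
            class = "circ_cw_null")
}

#' Cross-wavelet spectrum of two series
#'
#' The cross-wavelet transform `W_a * Conj(W_b)` localises oscillations
#' shared by two standardised series: its magnitude is the cross power, its
#' argument the phase difference (positive phase = `a` leads `b`).  Cells
#' are marked significant when their cross power exceeds the upper
#' `1 - alpha` quantile of a surrogate null ([cw_null()]).
#'
#' @param a,b `circ_series` on identical grids.
#' @param config A [wavelet_config()].
#' @param null Optional precomputed `circ_cw_null` (must match the series
#'   length); if missing, one is simulated per `config`.
#' @return A `circ_xwt`: `times`, `periods`, `cross_power`, `phase`
#'   (radians in (-pi, pi]), `significant` mask, `coi`, plus the null used.
#' @export
cross_wavelet <- function(a, b, config = wavelet_config(), null = NULL) {
  sa <- series_values(a)
  sb <- series_values(b)
  if (length(sa$x) != length(sb$x) ||
      abs(sa$t[1] - sb$t[1]) > 1e-9 || abs(sa$dt - sb$dt) > 1e-12) {
    abort("`a` and `b` must share the same time grid; see `align_series()`.")
  }
  ca <- morlet_cwt(a, config)
  cb <- morlet_cwt(b, config)
  cross <- ca$coef * Conj(cb$coef)
  if (is.null(null)) {
    rho <- c(0, 0)
    if (config$null == "red") {
      rho <- vapply(list(sa$x, sb$x), function(x) {
        max(0, stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
      }, numeric(1))
    }
    null <- cw_null(length(sa$x), sa$dt, config, rho = rho)
  } else {
    stopifnot(inherits(null, "circ_cw_null"))
    if (abs(null$n - length(sa$x)) / length(sa$x) > 0.02) {
      abort("`null` was built for a clearly different series length.")
    }
  }
  cross_power <- Mod(cross)
  structure(list(
    times = ca$times, periods = ca$periods,
    cross_power = cross_power, phase = Arg(cross),
    significant = sweep(cross_power, 1, null$quantile, `>`),
    coi = ca$coi, alpha = null$alpha, null = null,
    names = c(ca$series_name, cb$series_name), config = config
  ), class = "circ_xwt")
}

#' @export
print.circ_xwt <- function(x, ...) {
  cat("<circ_xwt> ", x$names[1], " x ", x$names[2], "; ",
      round(100 * mean(x$significant), 1), "% of cells significant at alpha = ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' Convert a phase difference at a given period into a time lag
#'
#' `lag = phase * period / (2 * pi)`, in `(-period/2, period/2]`.  Positive
#' phase (and lag) means the first series leads the second.
#'
#' @param phase_diff Phase difference in radians, in (-pi, pi].
#' @param period Oscillation period, s.
#' @return Lag in seconds.
#' @examples
#' phase_to_lag(pi / 2, 25)   # 6.25 s
#' @export
phase_to_lag <- function(phase_diff, period) {
  if (any(period <= 0)) abort("`period` must be positive.")
  phase_diff * period / (2 * pi)
}

#' Summarise the lead/lag of a cross-wavelet spectrum at one period
#'
#' Power-weighted circular mean of the phase difference along the period row
#' nearest `period`, using cells outside the cone of influence (and, when
#' available, only significant ones), converted to seconds with
#' [phase_to_lag()].
#'
#' @param xwt A `circ_xwt`.
#' @param period Target period, s.
#' @param significant_only Restrict to significant cells when any exist at
#'   that period (default `TRUE`).
#' @return Lag in seconds; positive = first series leads.
#' @export
xwt_band_lag <- function(xwt, period, significant_only = TRUE) {
  row <- which.min(abs(log2(xwt$periods / period)))
  use <- xwt$periods[row] <= xwt$coi
  if (significant_only && any(xwt$significant[row, use])) {
    use <- use & xwt$significant[row, ]
  }
  if (!any(use)) abort("no usable cells at that period.")
  z <- sum(xwt$cross_power[row, use] * exp(1i * xwt$phase[row, use]))
  phase_to_lag(Arg(z), xwt$periods[row])
}

#' Period/frequency bookkeeping
#'
#' A spectral peak at period P seconds corresponds to a frequency of 1/P Hz
#' (a 25-s oscillation sits at 0.04 Hz, the boundary between the LF and VLF
#' heart-rate-variability bands).
#'
#' @param period Period(s), s.
#' @return Frequency in Hz.
#' @export
period_to_frequency <- function(period) {
  if (any(period <= 0)) abort("`period` must be positive.")
  1 / period
}
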