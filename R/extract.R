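# Beat-to-beat extraction: raw 400 Hz ECG / BP channels -> uniform 10 Hz
# series iSBP, iHR, iAmp (and PPG-iAmp, LDF).

#' Remove baseline wander from an ECG with a Savitzky–Golay baseline
#'
#' A long-window, low-order Savitzky–Golay smooth follows the slow baseline
#' but not the narrow QRS complexes; subtracting it removes wander and DC
#' offset while leaving beat morphology intact.
#'
#' @param x Numeric ECG signal.
#' @param fs Sampling rate, Hz.
#' @param window Smoothing window length in seconds (default 1.0).
#' @param polyorder Polynomial order of the filter (default 3).
#' @return The baseline-corrected signal.
#' @export
remove_baseline_wander <- function(x, fs, window = 1, polyorder = 3) {
  n_win <- round(window * fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win > length(x)) abort("`window` is longer than the recording.")
  if (n_win < polyorder + 2) abort("`window` too short for `polyorder`.")
  baseline <- signal::sgolayfilt(x, p = polyorder, n = n_win)
  x - baseline
}

# Shared event detector: local maxima of a (centred) signal above a rolling
# robust-amplitude threshold, with refractory suppression.  Returns sample
# indices.
find_pulse_peaks <- function(x, fs, refractory = 0.25, frac = 0.4,
                             floor_mads = 10, chunk_s = 10) {
  n <- length(x)
  if (n < 3) return(integer())
  chunk_id <- pmin(ceiling(seq_len(n) / (chunk_s * fs)),
                   ceiling(n / (chunk_s * fs)))
  robmax <- tapply(x, chunk_id, quantile, probs = 0.995, names = FALSE)
  noise_floor <- floor_mads * mad(x)
  thr <- pmax(frac * as.numeric(robmax)[chunk_id], noise_floor)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_max & x > thr & x > 0)
  if (!length(cand)) return(integer())
  ref_n <- max(1L, round(refractory * fs))
  keep <- logical(length(cand))
  occupied <- logical(n)
  for (i in order(x[cand], decreasing = TRUE)) {
    idx <- cand[i]
    if (!occupied[idx]) {
      keep[i] <- TRUE
      lo <- max(1L, idx - ref_n)
      hi <- min(n, idx + ref_n)
      occupied[lo:hi] <- TRUE
    }
  }
  sort(cand[keep])
}

# refine each peak by a local least-squares parabola: averages sampling
# noise at the maximum and interpolates the sub-sample apex
refine_peaks <- function(x, idx, fs, halfwin = 2L) {
  n <- length(x)
  t <- (idx - 1) / fs
  v <- x[idx]
  for (j in seq_along(idx)) {
    i <- idx[j]
    lo <- max(1L, i - halfwin)
    hi <- min(n, i + halfwin)
    if (hi - lo < 2) next
    u <- (lo:hi) - i
    fit <- stats::lm.fit(cbind(1, u, u^2), x[lo:hi])
    a <- fit$coefficients
    if (is.na(a[3]) || a[3] >= 0) next
    apex <- -a[2] / (2 * a[3])
    if (abs(apex) <= halfwin) {
      t[j] <- t[j] + apex / fs
      v[j] <- a[1] - a[2]^2 / (4 * a[3])
    }
  }
  list(time = t, value = v)
}

#' Detect R-peaks and their amplitudes in a baseline-corrected ECG
#'
#' Candidate samples must be local maxima exceeding both a fraction of a
#' rolling robust maximum (the 99.5th percentile over 10-s chunks) and a
#' noise floor of `floor_mads` robust scale units; a refractory period then
#' keeps only the largest candidate per beat.  Adequate for sinus rhythm,
#' which is the intended regime.
#'
#' @param x Baseline-corrected ECG, mV (see [remove_baseline_wander()]).
#' @param fs Sampling rate, Hz.
#' @param refractory Minimum spacing between detections, s (default 0.25).
#' @param frac Fraction of the rolling robust maximum used as threshold.
#' @param floor_mads Noise floor in units of `mad(x)`; pure noise signals
#'   yield no detections.
#' @return A tibble with columns `time` (s) and `value` (R amplitude, mV).
#' @export
detect_r_peaks <- function(x, fs, refractory = 0.25, frac = 0.4,
                           floor_mads = 10) {
  idx <- find_pulse_peaks(x, fs, refractory, frac, floor_mads)
  if (!length(idx) && length(x) / fs >= 5) {
    warn("no R-peaks detected in a signal of 5 s or longer")
  }
  ref <- refine_peaks(x, idx, fs)
  tibble(time = ref$time, value = ref$value)
}

#' Detect per-cycle systolic maxima in an arterial pressure (or pulse) signal
#'
#' The signal is centred by subtracting a 1-s running median so that a
#' rolling-threshold local-maximum search (the same detector as for R-peaks)
#' finds one systolic peak per cardiac cycle; the reported value is the raw
#' signal at the peak, in the channel's units.
#'
#' @param x Arterial pressure (mmHg) or other pulse signal (e.g. PPG).
#' @param fs Sampling rate, Hz.
#' @param refractory,frac As in [detect_r_peaks()].
#' @param floor_mads Noise floor in robust scale units of the centred signal.
#'   The default is low (1) because the centred pulse waveform itself
#'   dominates the robust scale, unlike the ECG where the QRS is sparse.
#' @return A tibble with columns `time` (s) and `value`.
#' @export
detect_systolic_peaks <- function(x, fs, refractory = 0.25, frac = 0.4,
                                  floor_mads = 1) {
  k <- round(fs)
  if (k %% 2 == 0) k <- k + 1
  centred <- if (length(x) > k) x - stats::runmed(x, k) else x - median(x)
  idx <- find_pulse_peaks(centred, fs, refractory, frac, floor_mads)
  if (!length(idx) && length(x) / fs >= 5) {
    warn("no systolic peaks detected in a signal of 5 s or longer")
  }
  ref <- refine_peaks(x, idx, fs, halfwin = 4L)
  tibble(time = ref$time, value = ref$value)
}

#' Beat-to-beat heart rate from R-peak times
#'
#' `HR_i = 60 / RR_i`, with `RR_i` the interval in seconds between R-peak i
#' and i + 1.  Each HR value is stamped at the midpoint of its RR interval,
#' where it best represents the instantaneous rate (see the methods
#' vignette); `at = "start"` stamps it at R-peak i instead.
#'
#' @param times Strictly increasing R-peak times, s (length >= 2).
#' @param at Timestamp convention, `"midpoint"` (default) or `"start"`.
#' @return A tibble with columns `time` (s) and `value` (bpm), one row per
#'   RR interval (one fewer than the number of peaks).
#' @examples
#' compute_hr(c(0, 1, 1.5, 2.5))$value   # 60 120 60
#' @export
compute_hr <- function(times, at = c("midpoint", "start")) {
  at <- match.arg(at)
  if (length(times) < 2) abort("need at least two R-peak times.")
  rr <- diff(times)
  if (any(rr <= 0)) abort("R-peak times must be strictly increasing.")
  stamp <- if (at == "midpoint") times[-length(times)] + rr / 2 else
    times[-length(times)]
  tibble(time = stamp, value = 60 / rr)
}

#' Remove outlier beats by a sliding-window robust rule
#'
#' A beat value is dropped when it deviates from the median of its
#' surrounding window by more than `k` times the window MAD.  Noise episodes
#' misclassified as heartbeats produce such outliers in SBP, RR and
#' R-amplitude series.  Windows with zero MAD (constant data) flag nothing.
#'
#' The screen is repeated on the surviving beats until no beat is flagged
#' (a removal shifts the windows of its neighbours), so applying it twice
#' equals applying it once.
#'
#' @param beats Tibble with `time` and `value` columns (>= 5 rows).
#' @param k Threshold in robust scale units (default 4).
#' @param window Window size in beats (default 61, i.e. +/-30 beats).
#' @return The tibble with outliers removed; the total number removed is
#'   attached as attribute `"n_removed"`.
#' @export
remove_outliers <- function(beats, k = 4, window = 61) {
  if (nrow(beats) < 5) abort("need at least 5 beats for outlier screening.")
  half <- window %/% 2
  removed <- 0L
  repeat {
    v <- beats$value
    n <- length(v)
    flag <- vapply(seq_len(n), function(i) {
      win <- v[max(1, i - half):min(n, i + half)]
      s <- mad(win)
      s > 0 && abs(v[i] - median(win)) > k * s
    }, logical(1))
    if (all(flag)) abort("all beats flagged as outliers; input looks degenerate.")
    if (!any(flag)) break
    removed <- removed + sum(flag)
    beats <- beats[!flag, ]
  }
  attr(beats, "n_removed") <- removed
  beats
}

#' Interpolate a beat series to a uniform grid by natural cubic spline
#'
#' Events are splined onto a uniform grid (default 10 Hz) aligned to whole
#' multiples of the sampling interval, spanning from the first to the last
#' event — no extrapolation.  Aligning grids to the absolute clock means
#' series extracted from different channels of one recording share sample
#' times and can be compared directly.
#'
#' @param beats Tibble with `time` and `value` columns (>= 4 rows).
#' @param fs Output sampling rate, Hz (default 10).
#' @param name Optional series name (e.g. `"iSBP"`).
#' @return A `circ_series`: tibble with `time` and `value`, and attributes
#'   `fs` and `name`.
#' @export
interpolate_to_uniform <- function(beats, fs = 10, name = NULL) {
  if (nrow(beats) < 4) abort("need at least 4 events to spline.")
  t0 <- ceiling(beats$time[1] * fs) / fs
  t1 <- floor(beats$time[nrow(beats)] * fs + 1e-9) / fs
  grid <- seq(t0, t1, by = 1 / fs)
  sp <- spline(beats$time, beats$value, xout = grid, method = "natural",
               ties = "ordered")
  new_series(tibble(time = sp$x, value = sp$y), fs = fs, name = name)
}

new_series <- function(df, fs, name = NULL) {
  structure(df, fs = fs, name = name %||% "series",
            class = c("circ_series", class(df)))
}

#' @export
print.circ_series <- function(x, ...) {
  cat("<circ_series> ", attr(x, "name"), ": ", nrow(x), " samples at ",
      attr(x, "fs"), " Hz\n", sep = "")
  NextMethod()
}

#' Pulse-amplitude series from a photoplethysmogram
#'
#' The PPG goes through the same path as the arterial pressure: per-cycle
#' maxima, sliding-window outlier removal, natural-spline interpolation to a
#' uniform grid.
#'
#' @param x PPG signal, a.u.
#' @param fs Sampling rate, Hz.
#' @param fs_out Output rate, Hz (default 10).
#' @param k Outlier threshold, robust scale units.
#' @return A `circ_series` named `"PPG-iAmp"`.
#' @export
extract_ppg_amplitude <- function(x, fs, fs_out = 10, k = 4) {
  peaks <- detect_systolic_peaks(x, fs)
  peaks <- remove_outliers(peaks, k = k)
  interpolate_to_uniform(peaks, fs = fs_out, name = "PPG-iAmp")
}

#' Downsample a laser-Doppler-flow signal
#'
#' Anti-alias low-pass filtering (4th-order Butterworth applied forward and
#' backward, so with zero phase shift) followed by decimation.
#'
#' @param x LDF signal.
#' @param fs Input rate, Hz; must be an integer multiple of `fs_out`.
#' @param fs_out Output rate, Hz (default 10).
#' @param cutoff Low-pass cutoff, Hz (default 4, below the 5 Hz output
#'   Nyquist).
#' @return A `circ_series` named `"LDF"`.
#' @export
downsample_ldf <- function(x, fs, fs_out = 10, cutoff = 4) {
  if (fs_out > fs) abort("`fs_out` must not exceed the input rate.")
  factor <- fs / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    abort("`fs` must be an integer multiple of `fs_out`.")
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  m <- mean(x)
  smooth <- signal::filtfilt(bf, x - m) + m   # filter around the mean: a
                                              # constant signal passes exactly
  idx <- seq(1, length(x), by = round(factor))
  new_series(tibble(time = (idx - 1) / fs, value = smooth[idx]),
             fs = fs_out, name = "LDF")
}

#' Extract a sample-aligned segment of a recording
#'
#' @param recording A `circ_recording`.
#' @param start Segment start, s (>= 0).
#' @param length Segment length, s (default 1,800 = 30 min).
#' @return A `circ_recording` covering exactly `[start, start + length)`.
#' @export
select_segment <- function(recording, start, length = 1800) {
  stopifnot(inherits(recording, "circ_recording"))
  if (start < 0 || start + length > recording$duration + 1e-9) {
    abort("segment is outside the recording.")
  }
  fs <- recording$fs
  i0 <- round(start * fs) + 1
  n <- round(length * fs)
  out <- recording
  out$signals <- recording$signals[i0:(i0 + n - 1), ]
  out$duration <- length
  out$meta$segment_start <- start
  out
}

#' Extract all uniform 10 Hz series from a raw recording
#'
#' Runs the full preprocessing chain: Savitzky–Golay baseline removal and
#' R-peak detection on the ECG; systolic-peak detection on the BP; HR from
#' RR intervals; sliding-window outlier removal on SBP, HR and R-amplitude;
#' natural-spline interpolation of each to a uniform grid.  PPG and LDF
#' channels, when present, become `PPG-iAmp` and a downsampled `LDF`.
#'
#' @param recording A `circ_recording`.
#' @param fs_out Output rate, Hz (default 10).
#' @param k Outlier threshold (default 4 robust scale units).
#' @param hr_at HR timestamp convention, see [compute_hr()].
#' @return A list with `series` (named list of `circ_series`: `iSBP`, `iHR`,
#'   `iAmp`, and optionally `PPG-iAmp`, `LDF`) and `log` (a tibble of beats
#'   detected and outliers removed per variable).
#' @export
extract_series <- function(recording, fs_out = 10, k = 4,
                           hr_at = c("midpoint", "start")) {
  stopifnot(inherits(recording, "circ_recording"))
  hr_at <- match.arg(hr_at)
  sig <- recording$signals
  fs <- recording$fs
  if (!all(c("ecg", "bp") %in% names(sig))) {
    abort("recording must contain `ecg` and `bp` channels.")
  }

  ecg <- remove_baseline_wander(sig$ecg, fs)
  t_off <- sig$time[1]
  r_beats <- detect_r_peaks(ecg, fs)
  r_beats$time <- r_beats$time + t_off
  sbp_beats <- detect_systolic_peaks(sig$bp, fs)
  sbp_beats$time <- sbp_beats$time + t_off

  hr_beats <- compute_hr(r_beats$time, at = hr_at)

  amp_kept <- remove_outliers(r_beats, k = k)
  sbp_kept <- remove_outliers(sbp_beats, k = k)
  hr_kept <- remove_outliers(hr_beats, k = k)

  series <- list(
    iSBP = interpolate_to_uniform(sbp_kept, fs_out, "iSBP"),
    iHR = interpolate_to_uniform(hr_kept, fs_out, "iHR"),
    iAmp = interpolate_to_uniform(amp_kept, fs_out, "iAmp")
  )
  log <- tibble(
    variable = c("iSBP", "iHR", "iAmp"),
    beats_detected = c(nrow(sbp_beats), nrow(hr_beats), nrow(r_beats)),
    outliers_removed = c(attr(sbp_kept, "n_removed"),
                         attr(hr_kept, "n_removed"),
                         attr(amp_kept, "n_removed"))
  )

  if ("ppg" %in% names(sig)) {
    ppg <- extract_ppg_amplitude(sig$ppg, fs, fs_out)
    ppg$time <- ppg$time + t_off
    series[["PPG-iAmp"]] <- ppg
  }
  if ("ldf" %in% names(sig)) {
    ldf <- downsample_ldf(sig$ldf, fs, fs_out)
    ldf$time <- ldf$time + t_off
    series[["LDF"]] <- ldf
  }
  list(series = series, log = log)
}

#' Trim uniform series to their common time span
#'
#' Series extracted from one recording share clock-aligned grids but start
#' and end at their own first/last beats; this trims each to the overlap so
#' that pairwise analyses see identical grids.
#'
#' @param series Named list of `circ_series` at a common rate.
#' @return The list with every series restricted to the shared span.
#' @export
align_series <- function(series) {
  fs <- unique(vapply(series, attr, numeric(1), "fs"))
  if (length(fs) != 1) abort("series must share a sampling rate.")
  t0 <- max(vapply(series, function(s) s$time[1], numeric(1)))
  t1 <- min(vapply(series, function(s) s$time[nrow(s)], numeric(1)))
  if (t1 <= t0) abort("series do not overlap in time.")
  lapply(series, function(s) {
    out <- s[s$time >= t0 - 1e-9 & s$time <= t1 + 1e-9, ]
    new_series(out, fs = attr(s, "fs"), name = attr(s, "name"))
  })
}
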