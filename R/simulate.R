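# Synthetic circulatory-signal generator.
#
# Raw ECG and arterial-pressure channels are rendered at 400 Hz from a beat
# train produced by an integrate-and-fire rule on the instantaneous heart
# rate.  Slow sinusoidal modulations of HR, SBP and R-wave amplitude (with
# per-target lead/lag), respiration, baseline wander, white noise and
# transient noise episodes are all parameterised, and every injected feature
# is recorded in a ground-truth ledger so downstream stages can be validated.

MOD_TARGETS <- c("hr", "sbp", "r_amp", "ppg_amp")

#' Specify a slow sinusoidal modulation
#'
#' Describes one oscillatory component injected by the simulator: a sinusoid
#' of a given period applied to one or more beat-to-beat variables, with a
#' per-target lead relative to a common phase reference.
#'
#' @param period Oscillation period in seconds (must be positive; the study
#'   band of interest is 10–1,000 s).
#' @param targets Character vector, subset of `"hr"`, `"sbp"`, `"r_amp"`,
#'   `"ppg_amp"`.
#' @param depth Modulation amplitude per target, recycled if scalar: bpm for
#'   `"hr"`, mmHg for `"sbp"`, and a fraction of the base amplitude for
#'   `"r_amp"` / `"ppg_amp"`.  Must be non-negative.
#' @param lead_lag Seconds by which each target's sinusoid is advanced
#'   relative to the common reference (positive = leads).  `|lead_lag|` must
#'   be smaller than `period`.
#'
#' @return A tibble with one row per target and columns `target`, `period`,
#'   `depth`, `lead_lag`.
#' @examples
#' # a 25-s oscillation in which HR leads SBP by 3.5 s and SBP leads the
#' # R-wave amplitude by 8.2 s:
#' modulation_spec(25, c("hr", "sbp", "r_amp"),
#'                 depth = c(hr = 5, sbp = 5, r_amp = 0.1),
#'                 lead_lag = c(hr = 11.7, sbp = 8.2, r_amp = 0))
#' @export
modulation_spec <- function(period, targets, depth, lead_lag = 0) {
  stopifnot(is.numeric(period), length(period) == 1L)
  if (period <= 0) abort("`period` must be positive.")
  targets <- match.arg(targets, MOD_TARGETS, several.ok = TRUE)
  depth <- align_to_targets(depth, targets, "depth")
  lead_lag <- align_to_targets(lead_lag, targets, "lead_lag")
  if (any(depth < 0)) abort("`depth` must be non-negative.")
  if (any(abs(lead_lag) >= period)) {
    abort("`lead_lag` must be smaller than `period` in absolute value.")
  }
  tibble(target = targets, period = period, depth = depth, lead_lag = lead_lag)
}

align_to_targets <- function(x, targets, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(targets, names(x))
    if (length(missing)) {
      abort(paste0("`", what, "` is missing values for: ",
                   paste(missing, collapse = ", ")))
    }
    return(unname(x[targets]))
  }
  if (length(x) == 1L) return(rep(x, length(targets)))
  if (length(x) != length(targets)) {
    abort(paste0("`", what, "` must be scalar or one value per target."))
  }
  unname(x)
}

#' Specify the respiratory modulation
#'
#' Respiration is modelled as a fixed-period amplitude modulation of the
#' beat-to-beat variables.  Spontaneous breathing adds a modest modulation of
#' HR (respiratory sinus arrhythmia), SBP and R-amplitude; mechanical
#' ventilation uses a fixed ventilator period with a strong effect on SBP and
#' R-amplitude and none on HR.
#'
#' @param mode `"spontaneous"` or `"mechanical"`.
#' @param period Respiratory period in seconds.
#' @param depth_hr,depth_sbp,depth_amp Modulation depths (bpm, mmHg, and
#'   fraction of base amplitude respectively).
#' @return A list with class `"circ_resp"`.
#' @export
resp_spec <- function(mode = c("spontaneous", "mechanical"),
                      period = NULL,
                      depth_hr = NULL, depth_sbp = NULL, depth_amp = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    spontaneous = list(period = 4, depth_hr = 2, depth_sbp = 2, depth_amp = 0.03),
    mechanical  = list(period = 5, depth_hr = 0, depth_sbp = 8, depth_amp = 0.25)
  )
  out <- list(
    mode = mode,
    period = period %||% defaults$period,
    depth_hr = depth_hr %||% defaults$depth_hr,
    depth_sbp = depth_sbp %||% defaults$depth_sbp,
    depth_amp = depth_amp %||% defaults$depth_amp
  )
  if (out$period <= 0) abort("respiratory `period` must be positive.")
  structure(out, class = "circ_resp")
}

#' Configure the synthetic-recording generator
#'
#' Collects every parameter of the simulator.  Defaults describe a quiet
#' 30-min recording of a resting adult: 70 bpm, 120 mmHg systolic pressure
#' with a 40 mmHg pulse pressure, 1 mV R-waves, spontaneous respiration, and
#' white noise at 1% of each channel's signal scale.
#'
#' @param duration Recording length in seconds (default 1,800 = 30 min).
#' @param fs_raw Raw sampling rate in Hz (default 400).
#' @param base_hr Baseline heart rate, bpm; must lie in (20, 220).
#' @param base_sbp Baseline systolic pressure, mmHg.
#' @param pulse_pressure Systolic-minus-diastolic pressure, mmHg.
#' @param base_r_amp Baseline R-wave amplitude, mV.
#' @param modulations List of [modulation_spec()] tibbles.
#' @param respiration A [resp_spec()].
#' @param wander Baseline-wander sinusoid on the ECG:
#'   `list(period = s, amplitude = mV)`.
#' @param white_noise_sd Named per-channel white-noise standard deviations
#'   (`ecg` mV, `bp` mmHg, `ppg`, `ldf` a.u.).  `NULL` means 1% of each
#'   channel's amplitude scale.
#' @param noise_episodes Data frame (or list coercible to one) of transient
#'   noise episodes with columns `start`, `duration` (s) and `amplitude`
#'   (multiples of the channel's pulse scale); applied to the ECG and BP
#'   channels.
#' @param brody_gain Dimensionless coupling of R-amplitude to the SBP
#'   excursion (a preload surrogate); 0 disables it.
#' @param background Optional stochastic physiological background
#'   variability: a list `(hr_sd, sbp_sd, amp_sd, tau)` describing AR(1)
#'   (Ornstein–Uhlenbeck) fluctuations of HR (bpm), SBP (mmHg) and the
#'   amplitude channels (fraction), with correlation time `tau` seconds.
#'   `NULL` (default) disables it, leaving the injected modulations as the
#'   only slow structure.
#' @param channels Channels to render; subset of
#'   `c("ecg", "bp", "ppg", "ldf")`.
#' @param qrs_sigma Width (s) of the Gaussian QRS template.
#' @param sys_rise Time (s) from R-peak to the systolic maximum of the
#'   arterial-pulse template.
#' @param seed Integer seed; [generate_recording()] is deterministic given it.
#' @return A list with class `"circ_sim_config"`.
#' @seealso [generate_recording()], [sim_preset()]
#' @export
sim_config <- function(duration = 1800, fs_raw = 400,
                       base_hr = 70, base_sbp = 120, pulse_pressure = 40,
                       base_r_amp = 1,
                       modulations = list(),
                       respiration = resp_spec("spontaneous"),
                       wander = list(period = 5, amplitude = 0.05),
                       white_noise_sd = NULL,
                       noise_episodes = NULL,
                       brody_gain = 0,
                       background = NULL,
                       channels = c("ecg", "bp"),
                       qrs_sigma = 0.010, sys_rise = 0.15,
                       seed = 1L) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (base_hr <= 20 || base_hr >= 220) abort("`base_hr` must lie in (20, 220) bpm.")
  # QRS template bandwidth ~ 1/(2*pi*qrs_sigma); require comfortable sampling
  if (fs_raw <= 2 / (pi * qrs_sigma)) {
    abort("`fs_raw` is too low for the QRS template width.")
  }
  channels <- match.arg(channels, c("ecg", "bp", "ppg", "ldf"), several.ok = TRUE)
  if (inherits(modulations, "data.frame")) modulations <- list(modulations)
  mods <- if (length(modulations)) dplyr::bind_rows(modulations) else
    tibble(target = character(), period = numeric(),
           depth = numeric(), lead_lag = numeric())
  default_sd <- c(ecg = 0.01 * base_r_amp, bp = 0.01 * pulse_pressure,
                  ppg = 0.01, ldf = 0.02)
  if (is.null(white_noise_sd)) {
    white_noise_sd <- default_sd
  } else {
    stopifnot(!is.null(names(white_noise_sd)))
    default_sd[names(white_noise_sd)] <- white_noise_sd
    white_noise_sd <- default_sd
  }
  if (!is.null(noise_episodes)) {
    noise_episodes <- as_tibble(as.data.frame(noise_episodes))
    stopifnot(all(c("start", "duration") %in% names(noise_episodes)))
    if (!"amplitude" %in% names(noise_episodes)) noise_episodes$amplitude <- 3
  }
  structure(list(
    duration = duration, fs_raw = fs_raw,
    base_hr = base_hr, base_sbp = base_sbp, pulse_pressure = pulse_pressure,
    base_r_amp = base_r_amp,
    modulations = mods, respiration = respiration, wander = wander,
    white_noise_sd = white_noise_sd, noise_episodes = noise_episodes,
    brody_gain = brody_gain, background = background, channels = channels,
    qrs_sigma = qrs_sigma, sys_rise = sys_rise,
    seed = as.integer(seed)
  ), class = "circ_sim_config")
}

#' Ready-made simulation configurations
#'
#' Four configurations that emulate the perioperative situations studied by
#' the pipeline:
#'
#' * `"slow25"` — a pronounced 25-s oscillation in HR, SBP and R-amplitude,
#'   HR leading SBP by 3.5 s and SBP leading R-amplitude by 8.2 s
#'   (a preoperative, situation-A-like recording).
#' * `"ventilated"` — mechanical ventilation dominating the amplitude
#'   channels, plus a slow 60-s oscillation of HR only (situation-B-like).
#' * `"artifact"` — no slow modulation, but three 5-s high-amplitude noise
#'   episodes spaced 800 s apart (the "noise read as an oscillation" case).
#' * `"quiet"` — no slow modulation and no episodes (matched control).
#'
#' @param preset One of `"slow25"`, `"ventilated"`, `"artifact"`, `"quiet"`.
#' @param seed Integer seed passed to [sim_config()].
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `"circ_sim_config"`.
#' @export
sim_preset <- function(preset = c("slow25", "ventilated", "artifact", "quiet"),
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    slow25 = list(
      modulations = list(modulation_spec(
        25, c("hr", "sbp", "r_amp"),
        depth = c(hr = 5, sbp = 5, r_amp = 0.10),
        lead_lag = c(hr = 11.7, sbp = 8.2, r_amp = 0))),
      # a single oscillatory component is the emulated condition, so the
      # respiratory modulation is switched off here (see the ventilated
      # preset for respiration-dominated recordings)
      respiration = resp_spec("spontaneous", depth_hr = 0, depth_sbp = 0,
                              depth_amp = 0)
    ),
    ventilated = list(
      modulations = list(modulation_spec(60, "hr", depth = 5)),
      respiration = resp_spec("mechanical"),
      # realistic continuum of slow background variability, against which
      # "no distinct iAmp peak" is judged
      background = list(hr_sd = 2, sbp_sd = 2, amp_sd = 0.02, tau = 30)
    ),
    artifact = list(
      noise_episodes = data.frame(start = c(95, 895, 1695),
                                  duration = 5, amplitude = 3)
    ),
    quiet = list()
  )
  do.call(sim_config, utils::modifyList(args, list(seed = seed, ...)))
}

# sum of the injected sinusoids for one target, evaluated at times t;
# respiration is included as an extra fixed-period term
target_modulation <- function(t, config, target) {
  mods <- config$modulations
  out <- numeric(length(t))
  rows <- which(mods$target == target)
  for (i in rows) {
    out <- out + mods$depth[i] *
      sin(2 * pi * (t + mods$lead_lag[i]) / mods$period[i])
  }
  resp <- config$respiration
  depth <- switch(target, hr = resp$depth_hr, sbp = resp$depth_sbp,
                  r_amp = resp$depth_amp, ppg_amp = resp$depth_amp)
  out + depth * sin(2 * pi * t / resp$period)
}

# AR(1) / Ornstein-Uhlenbeck background fluctuation with stationary sd and
# correlation time tau, sampled at spacing dt
ou_series <- function(n, sd, tau, dt) {
  if (is.null(sd) || sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - a^2)), a,
                           method = "recursive"))
}

#' Place heartbeats by integrate-and-fire on the instantaneous heart rate
#'
#' The instantaneous heart rate is the baseline plus all HR-targeted
#' modulations (including respiratory sinus arrhythmia).  Its time integral
#' is accumulated and a beat fires at every whole cycle, so that each RR
#' interval is the time over which the instantaneous rate integrates to one
#' beat — downstream, `HR = 60/RR` then recovers the injected modulation.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of beat (R-peak) times in seconds; the first beat
#'   is at t = 0 and the last at or before `duration`.
#' @export
generate_beat_times <- function(config) {
  stopifnot(inherits(config, "circ_sim_config"))
  dt <- 1 / config$fs_raw
  t <- seq(0, config$duration, by = dt)
  f <- config$base_hr + target_modulation(t, config, "hr")
  if (!is.null(config$background)) {
    f <- f + ou_series(length(t), config$background$hr_sd,
                       config$background$tau, dt)
  }
  if (any(f <= 0)) abort("instantaneous heart rate became non-positive; reduce modulation depths.")
  # trapezoidal cumulative beat count
  cycles <- c(0, cumsum((f[-1] + f[-length(f)]) / 2) * dt / 60)
  n_beats <- floor(cycles[length(cycles)])
  if (n_beats < 1) return(numeric())
  crossings <- approx(cycles, t, xout = seq_len(n_beats), ties = "ordered")$y
  # keep only beats whose QRS template is fully inside the recording
  crossings[crossings <= config$duration - 6 * config$qrs_sigma]
}

#' Render an ECG channel from beat times and per-beat R-amplitudes
#'
#' Each beat becomes a Gaussian QRS-like deflection of width
#' `config$qrs_sigma` whose maximum equals the per-beat amplitude, centred on
#' the beat time.  Baseline wander (a slow sinusoid) and white noise are
#' added per the configuration.
#'
#' @param beat_times Beat times, s.
#' @param r_amps Per-beat R amplitudes, mV (same length as `beat_times`).
#' @param config A [sim_config()].
#' @param add_noise,add_wander Logical switches, mainly for tests.
#' @return Numeric signal of length `round(duration * fs_raw)`, mV.
#' @export
synthesize_ecg <- function(beat_times, r_amps, config,
                           add_noise = TRUE, add_wander = TRUE) {
  stopifnot(length(beat_times) == length(r_amps))
  n <- round(config$duration * config$fs_raw)
  t <- (seq_len(n) - 1) / config$fs_raw
  y <- numeric(n)
  sig <- config$qrs_sigma
  if (length(beat_times)) {
    prev <- findInterval(t, beat_times)
    for (shift in 0:1) {                # nearest beat on either side
      j <- prev + shift
      ok <- j >= 1 & j <= length(beat_times)
      d <- abs(t[ok] - beat_times[j[ok]])
      near <- d < 6 * sig
      idx <- which(ok)[near]
      y[idx] <- y[idx] + r_amps[j[idx]] * exp(-0.5 * (d[near] / sig)^2)
    }
  }
  if (add_wander && !is.null(config$wander) && config$wander$amplitude > 0) {
    y <- y + config$wander$amplitude * sin(2 * pi * t / config$wander$period)
  }
  if (add_noise && config$white_noise_sd[["ecg"]] > 0) {
    y <- y + rnorm(n, 0, config$white_noise_sd[["ecg"]])
  }
  y
}

# arterial pulse template: gamma-like rise to 1 at tau = sys_rise, slower decay
pulse_template <- function(tau, sys_rise) {
  g <- numeric(length(tau))
  pos <- tau > 0
  x <- tau[pos] / sys_rise
  g[pos] <- x^2 * exp(2 * (1 - x))
  g
}

#' Render an arterial blood-pressure channel
#'
#' Each cardiac cycle is an asymmetric pulse (fast systolic upstroke, slower
#' decay) rising from the diastolic baseline to the per-beat systolic value.
#' The systolic maximum occurs `config$sys_rise` seconds after the R-peak.
#'
#' @param beat_times Beat (R-peak) times, s.
#' @param sbp_values Per-beat systolic maxima, mmHg.
#' @param config A [sim_config()].
#' @param add_noise Logical.
#' @return Numeric signal, mmHg.  An empty beat list gives a flat signal at
#'   the diastolic baseline.
#' @export
synthesize_bp <- function(beat_times, sbp_values, config, add_noise = TRUE) {
  stopifnot(length(beat_times) == length(sbp_values))
  n <- round(config$duration * config$fs_raw)
  t <- (seq_len(n) - 1) / config$fs_raw
  pp <- config$pulse_pressure
  y <- rep(config$base_sbp - pp, n)
  if (length(beat_times)) {
    prev <- findInterval(t, beat_times)
    has <- prev >= 1
    tau <- t[has] - beat_times[prev[has]]
    g <- pulse_template(tau, config$sys_rise)
    y[has] <- (sbp_values[prev[has]] - pp) + pp * g
  }
  if (add_noise && config$white_noise_sd[["bp"]] > 0) {
    y <- y + rnorm(n, 0, config$white_noise_sd[["bp"]])
  }
  y
}

# merge overlapping [start, start+duration] intervals; warn when merging
merge_episodes <- function(episodes) {
  ep <- dplyr::arrange(episodes, .data$start)
  ep$end <- ep$start + ep$duration
  out <- ep[1, ]
  for (i in seq_len(nrow(ep))[-1]) {
    last <- nrow(out)
    if (ep$start[i] <= out$end[last]) {
      warn("overlapping noise episodes merged")
      out$end[last] <- max(out$end[last], ep$end[i])
      out$amplitude[last] <- max(out$amplitude[last], ep$amplitude[i])
    } else {
      out <- dplyr::bind_rows(out, ep[i, ])
    }
  }
  out$duration <- out$end - out$start
  out
}

#' Superimpose transient noise episodes on a signal
#'
#' Adds high-amplitude white-noise bursts inside the stated intervals and
#' leaves the signal untouched elsewhere.  Overlapping episodes are merged
#' with a warning; episodes outside the recording are an error.
#'
#' @param x Numeric signal.
#' @param episodes Data frame with columns `start`, `duration` (s) and
#'   `amplitude` (noise SD in multiples of `scale`).
#' @param fs Sampling rate of `x`, Hz.
#' @param scale Channel amplitude scale that `amplitude` multiplies.
#' @return The signal with episodes injected; the merged episode intervals
#'   are attached as attribute `"episodes"`.
#' @export
inject_noise_episodes <- function(x, episodes, fs, scale = 1) {
  if (is.null(episodes) || nrow(episodes) == 0) return(x)
  episodes <- as_tibble(as.data.frame(episodes))
  dur <- length(x) / fs
  if (any(episodes$start < 0) ||
      any(episodes$start + episodes$duration > dur + 1e-9)) {
    abort("noise episode outside the recording bounds.")
  }
  merged <- merge_episodes(episodes)
  for (i in seq_len(nrow(merged))) {
    idx <- which((seq_along(x) - 1) / fs >= merged$start[i] &
                 (seq_along(x) - 1) / fs < merged$end[i])
    x[idx] <- x[idx] + rnorm(length(idx), 0, merged$amplitude[i] * scale)
  }
  attr(x, "episodes") <- merged
  x
}

#' Generate a synthetic circulatory recording with its ground-truth ledger
#'
#' Composes the full simulation: beat placement, per-beat SBP / R-amplitude
#' values (slow modulations, respiration, optional Brody coupling), channel
#' rendering, baseline wander, white noise, and transient noise episodes.
#' The returned ledger holds the true beat times, per-beat values and
#' episode intervals, and is the oracle for recovery tests.
#'
#' Per-beat SBP is evaluated at the systolic instant (`sys_rise` after the
#' R-peak), which is where the value is observable in the pressure channel;
#' R-amplitude is evaluated at the R-peak itself.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recording` (class `"circ_recording"`:
#'   `signals` tibble with a `time` column plus one column per channel, `fs`,
#'   `duration`, `units`, `meta`) and `ledger` (class `"circ_ledger"`:
#'   `beats` tibble with `time`, `sys_time`, `sbp`, `r_amp`; `hr` tibble with
#'   interval-midpoint `time` and `hr`; `modulations`; `noise_episodes`).
#'   Deterministic given `config$seed`.
#' @examples
#' rec <- generate_recording(sim_config(duration = 60, seed = 42))
#' head(rec$recording$signals)
#' head(rec$ledger$beats)
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "circ_sim_config"))
  withr::with_seed(config$seed, {
    bt <- generate_beat_times(config)
    sys_t <- bt + config$sys_rise
    bg <- config$background
    mean_rr <- if (length(bt) > 1) mean(diff(bt)) else 60 / config$base_hr
    sbp <- config$base_sbp + target_modulation(sys_t, config, "sbp") +
      ou_series(length(bt), bg$sbp_sd, bg$tau %||% 30, mean_rr)
    r_amp <- config$base_r_amp *
      (1 + target_modulation(bt, config, "r_amp") +
         ou_series(length(bt), bg$amp_sd, bg$tau %||% 30, mean_rr)) +
      config$brody_gain * (sbp - config$base_sbp) / config$pulse_pressure *
        config$base_r_amp
    hr <- 60 / diff(bt)
    hr_t <- (bt[-1] + bt[-length(bt)]) / 2

    n <- round(config$duration * config$fs_raw)
    t <- (seq_len(n) - 1) / config$fs_raw
    sig <- list()
    sig$ecg <- synthesize_ecg(bt, r_amp, config)
    sig$bp <- synthesize_bp(bt, sbp, config)
    if ("ppg" %in% config$channels) {
      ppg_amp <- 1 + target_modulation(bt, config, "ppg_amp") +
        ou_series(length(bt), bg$amp_sd, bg$tau %||% 30, mean_rr)
      pcfg <- config
      pcfg$pulse_pressure <- 1
      pcfg$base_sbp <- 1           # baseline 0, pulse height = ppg_amp
      prev <- findInterval(t, bt)
      y <- numeric(n)
      has <- prev >= 1
      y[has] <- ppg_amp[prev[has]] * pulse_template(t[has] - bt[prev[has]],
                                                    config$sys_rise)
      sig$ppg <- y + rnorm(n, 0, config$white_noise_sd[["ppg"]])
    }
    if ("ldf" %in% config$channels) {
      z <- stats::filter(rnorm(n), rep(1, config$fs_raw * 2) / (config$fs_raw * 2),
                         circular = TRUE)
      sig$ldf <- 10 + config$white_noise_sd[["ldf"]] * as.numeric(z) /
        sd(as.numeric(z))
    }
    episodes <- NULL
    if (!is.null(config$noise_episodes) && nrow(config$noise_episodes)) {
      sig$ecg <- inject_noise_episodes(sig$ecg, config$noise_episodes,
                                       config$fs_raw, config$base_r_amp)
      episodes <- attr(sig$ecg, "episodes")
      attr(sig$ecg, "episodes") <- NULL
      sig$bp <- as.numeric(inject_noise_episodes(sig$bp, config$noise_episodes,
                                                 config$fs_raw,
                                                 config$pulse_pressure))
    }
    signals <- as_tibble(c(list(time = t), sig[intersect(config$channels, names(sig))]))

    recording <- structure(list(
      signals = signals, fs = config$fs_raw, duration = config$duration,
      units = c(ecg = "mV", bp = "mmHg", ppg = "a.u.",
                ldf = "a.u.")[intersect(config$channels, names(sig))],
      meta = list(seed = config$seed, config = config)
    ), class = "circ_recording")

    ledger <- structure(list(
      beats = tibble(time = bt, sys_time = sys_t, sbp = sbp, r_amp = r_amp),
      hr = tibble(time = hr_t, hr = hr),
      modulations = config$modulations,
      noise_episodes = if (is.null(episodes)) {
        tibble(start = numeric(), end = numeric(), amplitude = numeric())
      } else {
        episodes[, c("start", "end", "amplitude")]
      },
      config = config
    ), class = "circ_ledger")

    list(recording = recording, ledger = ledger)
  })
}

#' @export
print.circ_recording <- function(x, ...) {
  cat("<circ_recording> ", x$duration, " s at ", x$fs, " Hz; channels: ",
      paste(setdiff(names(x$signals), "time"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.circ_ledger <- function(x, ...) {
  cat("<circ_ledger> ", nrow(x$beats), " beats; ",
      nrow(x$modulations), " modulation target(s); ",
      nrow(x$noise_episodes), " noise episode(s)\n", sep = "")
  invisible(x)
}
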