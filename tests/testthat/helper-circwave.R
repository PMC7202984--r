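# Shared fixtures, all built in code.

# uniform series constructor used throughout the tests
make_series <- function(values, fs = 10, t0 = 0, name = "test") {
  structure(tibble::tibble(time = t0 + (seq_along(values) - 1) / fs,
                           value = values),
            fs = fs, name = name,
            class = c("circ_series", class(tibble::tibble())))
}

sinusoid_series <- function(period, duration, fs = 10, amplitude = 1,
                            phase_shift = 0, noise_sd = 0, t0 = 0) {
  t <- t0 + seq(0, duration - 1 / fs, by = 1 / fs)
  make_series(amplitude * sin(2 * pi * (t - phase_shift) / period) +
                rnorm(length(t), 0, noise_sd),
              fs = fs, t0 = t0, name = paste0("sin", period))
}

# a short, fully deterministic simulation for unit tests (no stochastic
# background, no respiratory modulation)
clean_sim_config <- function(duration = 300, seed = 1, ...) {
  sim_config(
    duration = duration,
    modulations = list(modulation_spec(
      25, c("hr", "sbp", "r_amp"),
      depth = c(hr = 5, sbp = 5, r_amp = 0.1),
      lead_lag = c(hr = 11.7, sbp = 8.2, r_amp = 0))),
    respiration = resp_spec("spontaneous", depth_hr = 0, depth_sbp = 0,
                            depth_amp = 0),
    seed = seed, ...)
}

# wavelet configuration light enough for unit tests
test_wavelet_config <- function(...) {
  wavelet_config(n_surrogates = 20, ...)
}

# FFT periodogram oracle: period of the strongest Fourier component
fft_peak_period <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  half <- 2:floor(n / 2)
  freq <- (half - 1) * fs / n
  1 / freq[which.max(p[half])]
}
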