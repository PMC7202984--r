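test_that("constant-rate configs give exactly periodic beats", {
  no_resp <- resp_spec(depth_hr = 0, depth_sbp = 0, depth_amp = 0)
  cfg <- sim_config(duration = 120, base_hr = 60, respiration = no_resp,
                    seed = 1)
  bt <- generate_beat_times(cfg)
  expect_true(all(abs(diff(bt) - 1) < 1e-9))
  expect_gte(bt[1], 0)
  expect_lte(max(bt), 120)

  cfg10 <- sim_config(duration = 10, base_hr = 60, respiration = no_resp,
                      seed = 1)
  expect_lte(abs(length(generate_beat_times(cfg10)) - 10), 1)
})

test_that("an HR modulation appears in the RR sequence at the right frequency", {
  cfg <- sim_config(duration = 600, base_hr = 60,
                    modulations = list(modulation_spec(25, "hr", depth = 5)),
                    respiration = resp_spec(depth_hr = 0, depth_sbp = 0,
                                            depth_amp = 0),
                    seed = 1)
  bt <- generate_beat_times(cfg)
  rr <- diff(bt)
  # mean RR over whole minutes stays ~1 s (modulation integrates to zero)
  expect_equal(mean(rr), 1, tolerance = 5e-3)
  # FFT oracle on the (nearly 1 Hz) RR sequence: peak at 0.04 Hz
  peak_period <- fft_peak_period(rr, fs = 1 / mean(rr))
  expect_equal(1 / peak_period, 0.04, tolerance = 0.005)
})

test_that("unphysiological configs are rejected", {
  expect_error(sim_config(duration = -5), "duration")
  expect_error(sim_config(base_hr = 10), "base_hr")
  expect_error(modulation_spec(0, "hr", 1), "period")
  expect_error(modulation_spec(25, "hr", depth = -1), "depth")
  expect_error(modulation_spec(25, "hr", depth = 1, lead_lag = 30), "lead_lag")
  # instantaneous HR driven non-positive
  bad <- sim_config(duration = 60, base_hr = 30,
                    modulations = list(modulation_spec(25, "hr", depth = 40)),
                    respiration = resp_spec(depth_hr = 0, depth_sbp = 0,
                                            depth_amp = 0))
  expect_error(generate_beat_times(bad), "non-positive")
})

test_that("rendered ECG beats peak at the requested amplitude and time", {
  cfg <- sim_config(duration = 4, seed = 1,
                    wander = list(period = 5, amplitude = 0))
  y <- synthesize_ecg(2, 1.0, cfg, add_noise = FALSE)
  expect_equal(max(y), 1.0, tolerance = 1e-3)
  expect_lte(abs((which.max(y) - 1) / 400 - 2), 1 / 400 + 1e-9)
})

test_that("per-beat ECG maxima track an amplitude modulation", {
  cfg <- clean_sim_config(duration = 300)
  gr <- withr::with_seed(1, {
    bt <- generate_beat_times(cfg)
    amps <- 1 + 0.1 * sin(2 * pi * bt / 25)
    list(bt = bt, amps = amps,
         y = synthesize_ecg(bt, amps, cfg, add_noise = FALSE,
                            add_wander = FALSE))
  })
  # maximum of the clean render around each beat
  idx <- round(gr$bt * 400) + 1
  got <- vapply(idx, function(i) {
    max(gr$y[max(1, i - 10):min(length(gr$y), i + 10)])
  }, numeric(1))
  expect_gt(cor(got, gr$amps), 0.99)
})

test_that("baseline wander is additive by construction", {
  cfg <- sim_config(duration = 30, seed = 1,
                    wander = list(period = 5, amplitude = 0.3))
  bt <- generate_beat_times(cfg)
  amps <- rep(1, length(bt))
  with_w <- synthesize_ecg(bt, amps, cfg, add_noise = FALSE, add_wander = TRUE)
  without <- synthesize_ecg(bt, amps, cfg, add_noise = FALSE, add_wander = FALSE)
  t <- (seq_along(with_w) - 1) / 400
  expect_equal(with_w - without, 0.3 * sin(2 * pi * t / 5), tolerance = 1e-12)
})

test_that("arterial pulses peak at the per-beat systolic value", {
  cfg <- sim_config(duration = 60, base_hr = 60, seed = 1)
  bt <- generate_beat_times(cfg)
  y <- synthesize_bp(bt, rep(120, length(bt)), cfg, add_noise = FALSE)
  idx <- round((bt + cfg$sys_rise) * 400) + 1
  got <- vapply(idx, function(i) max(y[max(1, i - 20):min(length(y), i + 20)]),
                numeric(1))
  expect_true(all(abs(got - 120) < 1.2))   # within 1%

  # empty beat list: flat diastolic baseline
  flat <- synthesize_bp(numeric(), numeric(), cfg, add_noise = FALSE)
  expect_true(all(flat == 120 - 40))
})

test_that("noise episodes are local, merged when overlapping, and validated", {
  x <- rep(0, 400 * 30)
  withr::with_seed(1, {
    same <- inject_noise_episodes(x, data.frame(start = numeric(),
                                                duration = numeric(),
                                                amplitude = numeric())[0, ], 400)
    expect_identical(as.numeric(same), x)

    ep <- data.frame(start = 5, duration = 2, amplitude = 1)
    y <- inject_noise_episodes(x, ep, 400, scale = 2)
    t <- (seq_along(y) - 1) / 400
    expect_true(all(y[t < 5 | t >= 7] == 0))
    expect_gt(sd(y[t >= 5 & t < 7]), 1)

    expect_warning(
      inject_noise_episodes(x, data.frame(start = c(5, 6), duration = 2,
                                          amplitude = 1), 400),
      "merged")
    expect_error(
      inject_noise_episodes(x, data.frame(start = 29, duration = 5,
                                          amplitude = 1), 400),
      "bounds")
  })
})

test_that("generate_recording is deterministic and internally consistent", {
  cfg <- clean_sim_config(duration = 120, seed = 42)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$ledger$beats, b$ledger$beats)

  led <- a$ledger
  expect_true(all(diff(led$beats$time) > 0))
  expect_equal(nrow(led$hr), nrow(led$beats) - 1)
  expect_true(all(led$hr$hr > 0))
  expect_equal(led$hr$hr, 60 / diff(led$beats$time))
})

test_that("realized RR intervals respect the modulation depth bounds", {
  cfg <- clean_sim_config(duration = 600, seed = 3)
  rr <- diff(generate_beat_times(cfg))
  d <- 5
  eps <- 0.5
  expect_true(all(rr >= 60 / (70 + d + eps)))
  expect_true(all(rr <= 60 / (70 - d - eps)))
})

test_that("optional PPG and LDF channels are rendered", {
  cfg <- sim_config(duration = 60, seed = 2, channels = c("ecg", "bp", "ppg", "ldf"),
                    modulations = list(modulation_spec(25, "ppg_amp", depth = 0.2)))
  rec <- generate_recording(cfg)$recording
  expect_true(all(c("ppg", "ldf") %in% names(rec$signals)))
  expect_gt(max(rec$signals$ppg), 0.5)
  expect_equal(mean(rec$signals$ldf), 10, tolerance = 0.5)
})
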