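test_that("Savitzky-Golay baseline removal strips offset and slow wander", {
  withr::with_seed(1, {
    cfg <- sim_config(duration = 60, seed = 1,
                      wander = list(period = 5, amplitude = 0))
    bt <- generate_beat_times(cfg)
    ecg <- synthesize_ecg(bt, rep(1, length(bt)), cfg, add_noise = FALSE)

    out <- remove_baseline_wander(ecg + 0.5, 400)
    expect_lt(abs(mean(out)), 0.01)

    t <- (seq_along(ecg) - 1) / 400
    wander <- 0.3 * sin(2 * pi * t / 5)
    res <- remove_baseline_wander(ecg + wander, 400)
    # projection of the residual onto the injected wander
    resid_amp <- 2 * abs(mean(res * sin(2 * pi * t / 5)))
    expect_lt(resid_amp, 0.1 * 0.3)

    expect_identical(remove_baseline_wander(rep(0, 4000), 400), rep(0, 4000))
    expect_error(remove_baseline_wander(rep(0, 100), 400), "window")
  })
})

test_that("R-peak detection finds every clean beat and nothing in noise", {
  cfg <- sim_config(duration = 60, base_hr = 60, seed = 5)
  gr <- generate_recording(cfg)
  ecg <- remove_baseline_wander(gr$recording$signals$ecg, 400)
  peaks <- detect_r_peaks(ecg, 400)
  bt <- gr$ledger$beats$time
  expect_lte(abs(nrow(peaks) - 60), 1)
  nearest <- vapply(peaks$time, function(p) min(abs(p - bt)), numeric(1))
  expect_true(all(nearest <= 0.005))

  withr::with_seed(2, {
    expect_warning(none <- detect_r_peaks(rnorm(400 * 10, 0, 0.05), 400),
                   "no R-peaks")
    expect_equal(nrow(none), 0)
  })
})

test_that("detected amplitudes and systolic values track the ledger", {
  gr <- generate_recording(clean_sim_config(duration = 300, seed = 8))
  sig <- gr$recording$signals
  led <- gr$ledger$beats

  ra <- detect_r_peaks(remove_baseline_wander(sig$ecg, 400), 400)
  expect_equal(nrow(ra), nrow(led))
  expect_gt(cor(ra$value, led$r_amp), 0.99)

  sp <- detect_systolic_peaks(sig$bp, 400)
  expect_equal(nrow(sp), nrow(led))
  expect_gt(cor(sp$value, led$sbp), 0.99)
  expect_true(all(abs(sp$value - led$sbp) / led$sbp < 0.01))

  expect_equal(nrow(detect_systolic_peaks(rep(80, 400 * 10), 400)), 0)
})

test_that("compute_hr implements HR = 60/RR with the documented stamps", {
  expect_equal(compute_hr(c(0, 1, 2))$value, c(60, 60))
  expect_equal(compute_hr(c(0, 0.75))$value, 80)
  expect_equal(compute_hr(c(0, 1, 1.5, 2.5))$value, c(60, 120, 60))
  expect_equal(compute_hr(c(0, 1, 1.5, 2.5))$time, c(0.5, 1.25, 2))
  expect_equal(compute_hr(c(0, 1, 1.5, 2.5), at = "start")$time, c(0, 1, 1.5))
  expect_error(compute_hr(c(0, 1, 1)), "strictly increasing")
  expect_error(compute_hr(5), "two")
})

test_that("outlier screening matches a brute-force robust z-score oracle", {
  withr::with_seed(3, {
    v <- rnorm(200, 100, 1)
    clean <- tibble::tibble(time = as.numeric(seq_along(v)), value = v)
    kept <- remove_outliers(clean)
    expect_equal(nrow(kept), 200)
    expect_equal(attr(kept, "n_removed"), 0)

    spiked <- clean
    spiked$value[77] <- 100 + 10 * mad(v)
    # oracle: every point's robust z within its +/-30-beat window
    flag <- vapply(seq_len(200), function(i) {
      win <- spiked$value[max(1, i - 30):min(200, i + 30)]
      s <- mad(win)
      s > 0 && abs(spiked$value[i] - median(win)) > 4 * s
    }, logical(1))
    expect_identical(which(flag), 77L)
    got <- remove_outliers(spiked, k = 4)
    expect_identical(setdiff(spiked$time, got$time), 77)

    const <- tibble::tibble(time = 1:50, value = rep(5, 50))
    expect_equal(nrow(remove_outliers(const)), 50)
  })
})

test_that("outlier screening is idempotent on generated beat series", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      v <- 100 + rnorm(300) + c(rep(0, 150), 8, rep(0, 149))
      beats <- tibble::tibble(time = as.numeric(seq_along(v)), value = v)
      once <- remove_outliers(beats)
      twice <- remove_outliers(once)
      expect_identical(once$time, twice$time)
      expect_identical(once$value, twice$value)
      expect_equal(attr(twice, "n_removed"), 0)
    })
  }
})

test_that("natural-spline interpolation reproduces smooth signals", {
  withr::with_seed(4, {
    t_ev <- sort(runif(100, 0, 100))
    beats <- tibble::tibble(time = t_ev, value = sin(2 * pi * t_ev / 20))
    s <- interpolate_to_uniform(beats, 10)
    expect_equal(attr(s, "fs"), 10)
    truth <- sin(2 * pi * s$time / 20)
    expect_lt(max(abs(s$value - truth)), 0.01)

    # events already on the grid reproduce exactly at shared points
    ongrid <- tibble::tibble(time = seq(0, 5, by = 0.1),
                             value = rnorm(51))
    s2 <- interpolate_to_uniform(ongrid, 10)
    expect_equal(s2$value, ongrid$value, tolerance = 1e-10)

    expect_error(interpolate_to_uniform(ongrid[1:3, ]), "4 events")
  })
})

test_that("event times stay strictly increasing through the chain", {
  gr <- generate_recording(clean_sim_config(duration = 200, seed = 9))
  sig <- gr$recording$signals
  r <- detect_r_peaks(remove_baseline_wander(sig$ecg, 400), 400)
  expect_true(all(diff(r$time) > 0))
  hr <- compute_hr(r$time)
  expect_true(all(diff(hr$time) > 0))
  kept <- remove_outliers(hr)
  expect_true(all(diff(kept$time) > 0))
})

test_that("the PPG path equals the arterial path on identical input", {
  gr <- generate_recording(clean_sim_config(duration = 200, seed = 10))
  bp <- gr$recording$signals$bp
  via_ppg <- extract_ppg_amplitude(bp, 400)
  peaks <- remove_outliers(detect_systolic_peaks(bp, 400))
  via_bp <- interpolate_to_uniform(peaks, 10)
  expect_equal(via_ppg$value, via_bp$value, tolerance = 1e-12)
})

test_that("LDF downsampling preserves the passband and rejects above-Nyquist", {
  t <- seq(0, 100 - 1 / 400, by = 1 / 400)
  const <- downsample_ldf(rep(3, length(t)), 400)
  expect_true(all(abs(const$value - 3) < 1e-6))

  slow <- downsample_ldf(sin(2 * pi * t / 50), 400)
  expect_equal(max(abs(slow$value)), 1, tolerance = 0.01)

  lo <- downsample_ldf(sin(2 * pi * t * 1), 400)     # 1 Hz: kept
  hi <- downsample_ldf(sin(2 * pi * t * 6), 400)     # 6 Hz: rejected
  expect_gt(max(abs(lo$value[100:900])), 0.9)
  expect_lt(max(abs(hi$value[100:900])), 0.1)

  expect_error(downsample_ldf(rep(0, 100), 10, fs_out = 400), "exceed")
})

test_that("segment selection is an exact sample-aligned slice", {
  cfg <- sim_config(duration = 3600, seed = 11)
  rec <- generate_recording(cfg)$recording
  whole <- select_segment(rec, 0, 3600)
  expect_identical(whole$signals, rec$signals)

  seg <- select_segment(rec, 60, 1800)
  expect_equal(nrow(seg$signals), 720000)
  expect_equal(seg$signals$time[1], 60)
  expect_error(select_segment(rec, -1, 10), "outside")
  expect_error(select_segment(rec, 3000, 1800), "outside")
})

test_that("extraction recovers the injected modulations end to end", {
  gr <- generate_recording(clean_sim_config(duration = 600, seed = 12))
  ext <- extract_series(gr$recording)
  expect_named(ext$series, c("iSBP", "iHR", "iAmp"))
  expect_equal(ext$log$variable, c("iSBP", "iHR", "iAmp"))

  truths <- list(
    iSBP = function(t) 120 + 5 * sin(2 * pi * (t + 8.2) / 25),
    iHR = function(t) 70 + 5 * sin(2 * pi * (t + 11.7) / 25),
    iAmp = function(t) 1 + 0.1 * sin(2 * pi * t / 25)
  )
  for (v in names(truths)) {
    s <- ext$series[[v]]
    expect_gt(cor(s$value, truths[[v]](s$time)), 0.99)
  }

  # HR closure on the ledger's own beat times
  hr <- compute_hr(gr$ledger$beats$time)
  expect_equal(hr$value, 60 / diff(gr$ledger$beats$time), tolerance = 1e-12)
})
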