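test_that("the period grid and frequency bookkeeping are consistent", {
  cfg <- wavelet_config()
  per <- circwave:::wavelet_periods(cfg)
  expect_equal(min(per), 10)
  # the log2 grid is anchored at 10 s; its top sits within one voice of 1,024
  expect_lte(max(per), 1024)
  expect_lt(abs(log2(max(per) / 1024)), 1 / 12)
  expect_equal(diff(log2(per))[1], 1 / 12, tolerance = 1e-12)
  expect_equal(period_to_frequency(25), 0.04)
  expect_error(wavelet_config(alpha = 1.2), "alpha")
})

test_that("a stationary sinusoid peaks at its period, matching the FFT oracle", {
  withr::with_seed(1, {
    s <- sinusoid_series(25, 1800, noise_sd = 0.1)
    cw <- suppressWarnings(morlet_cwt(s))
    avg <- average_power(cw)
    got <- avg$period[which.max(avg$power)]
    oracle <- fft_peak_period(s$value, 10)
    expect_lte(abs(log2(got / oracle)), 1 / 12 + 1e-9)
    expect_lte(abs(log2(got / 25)), 1 / 12 + 1e-9)
  })
})

test_that("constant series carry no wavelet power", {
  s <- make_series(rep(3, 2000))
  cw <- morlet_cwt(s)
  expect_true(all(cw$power < 1e-20))
})

test_that("unstandardized power is quadratic in amplitude", {
  s1 <- sinusoid_series(25, 600)
  s2 <- make_series(2 * s1$value)
  p1 <- morlet_cwt(s1, standardize = FALSE)$power
  p2 <- morlet_cwt(s2, standardize = FALSE)$power
  expect_equal(p2, 4 * p1, tolerance = 1e-9)
})

test_that("stretching a sinusoid's period moves the power peak accordingly", {
  withr::with_seed(2, {
    peak_of <- function(period) {
      s <- sinusoid_series(period, 1800, noise_sd = 0.05)
      avg <- average_power(suppressWarnings(morlet_cwt(s)))
      avg$period[which.max(avg$power)]
    }
    p1 <- peak_of(30)
    p2 <- peak_of(60)
    expect_lte(abs(log2(p2 / p1) - 1), 2 / 12 + 1e-9)
  })
})

test_that("average power is unaffected by a circular time shift", {
  withr::with_seed(3, {
    x <- sin(2 * pi * seq(0, 1799.9, by = 0.1) / 50)
    a1 <- average_power(suppressWarnings(morlet_cwt(make_series(x))))
    a2 <- average_power(suppressWarnings(morlet_cwt(make_series(
      c(x[4501:18000], x[1:4500])))))
    keep <- !is.na(a1$power) & !is.na(a2$power) & a1$power > 1e-6
    expect_equal(a1$power[keep], a2$power[keep], tolerance = 0.05)
  })
})

test_that("average_power averages per period and flags empty periods", {
  fake <- structure(list(
    times = seq(0, 99.9, by = 0.1), periods = c(10, 20, 40),
    power = matrix(c(1, 2, 3), nrow = 3, ncol = 1000),
    coi = rep(50, 1000),
    series_name = "fake", config = wavelet_config()
  ), class = "circ_cwt")
  avg <- average_power(fake, exclude_coi = FALSE)
  expect_equal(avg$power, c(1, 2, 3))

  fake$coi <- rep(15, 1000)      # periods 20 and 40 entirely inside the coi
  avg2 <- average_power(fake, exclude_coi = TRUE)
  expect_equal(avg2$power[1], 1)
  expect_true(all(is.na(avg2$power[2:3])))
})

test_that("two injected modulations give two detected peaks, none when monotone", {
  withr::with_seed(4, {
    t <- seq(0, 1799.9, by = 0.1)
    s <- make_series(sin(2 * pi * t / 25) + sin(2 * pi * t / 100) +
                       rnorm(length(t), 0, 0.3))
    avg <- average_power(suppressWarnings(morlet_cwt(s)))
    pk <- find_spectral_peaks(avg)
    expect_equal(nrow(pk), 2)
    expect_lte(abs(log2(sort(pk$period)[1] / 25)), 1 / 12 + 1e-9)
    expect_lte(abs(log2(sort(pk$period)[2] / 100)), 1 / 12 + 1e-9)

    mono <- structure(tibble::tibble(period = c(10, 20, 40, 80),
                                     power = c(1, 2, 3, 4)),
                      class = c("circ_avgspec", class(tibble::tibble())))
    expect_equal(nrow(find_spectral_peaks(mono)), 0)
  })
})

test_that("white noise yields no reproducible spectral peak", {
  withr::with_seed(5, {
    peaks <- replicate(20, {
      s <- make_series(rnorm(6000))
      avg <- average_power(suppressWarnings(morlet_cwt(s)))
      avg$period[which.max(avg$power)]
    })
    expect_gt(length(unique(round(log2(peaks), 1))), 4)
  })
})

test_that("cross-wavelet phases encode lead/lag as documented", {
  withr::with_seed(6, {
    t <- seq(0, 899.9, by = 0.1)
    base <- sin(2 * pi * t / 25)
    a <- make_series(base + rnorm(length(t), 0, 0.02), name = "a")
    same <- make_series(base + rnorm(length(t), 0, 0.02), name = "b")
    cfg <- test_wavelet_config()
    null <- cw_null(length(t), 0.1, cfg)

    xw <- suppressWarnings(cross_wavelet(a, same, cfg, null = null))
    row <- which.min(abs(xw$periods - 25))
    use <- xw$significant[row, ] & xw$periods[row] <= xw$coi
    expect_gt(mean(use), 0.3)
    expect_lt(abs(mean(xw$phase[row, use])), 0.1)

    # b delayed by a quarter period: a leads, phase +pi/2
    delayed <- make_series(sin(2 * pi * (t - 6.25) / 25), name = "d")
    xw2 <- suppressWarnings(cross_wavelet(a, delayed, cfg, null = null))
    use2 <- xw2$significant[row, ] & xw2$periods[row] <= xw2$coi
    expect_equal(mean(xw2$phase[row, use2]), pi / 2, tolerance = 0.1)

    # conjugate symmetry of the phase
    xw3 <- suppressWarnings(cross_wavelet(delayed, a, cfg, null = null))
    expect_equal(xw3$phase, -xw2$phase, tolerance = 1e-9)

    short <- make_series(base[1:800], name = "short")
    expect_error(suppressWarnings(cross_wavelet(a, short, cfg)), "grid")
  })
})

test_that("phase differences convert to lags on the stated convention", {
  expect_equal(phase_to_lag(0, 25), 0)
  expect_equal(phase_to_lag(pi / 2, 25), 6.25)
  expect_error(phase_to_lag(1, -5), "period")

  withr::with_seed(7, {
    t <- seq(0, 899.9, by = 0.1)
    a <- make_series(sin(2 * pi * t / 25) + rnorm(length(t), 0, 0.05),
                     name = "lead")
    b <- make_series(sin(2 * pi * (t - 3.5) / 25) + rnorm(length(t), 0, 0.05),
                     name = "trail")
    cfg <- test_wavelet_config()
    xw <- suppressWarnings(cross_wavelet(a, b, cfg))
    expect_equal(xwt_band_lag(xw, 25), 3.5, tolerance = 0.2)
  })
})

test_that("the significance mask is calibrated on white noise", {
  withr::with_seed(8, {
    n <- 4000
    cfg <- test_wavelet_config(period_max = 256)
    null <- cw_null(n, 0.1, cfg, n_surrogates = 30)
    frac <- replicate(20, {
      a <- make_series(rnorm(n))
      b <- make_series(rnorm(n))
      mean(suppressWarnings(cross_wavelet(a, b, cfg, null = null))$significant)
    })
    expect_gt(mean(frac), 0.02)
    expect_lt(mean(frac), 0.09)
  })
})
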