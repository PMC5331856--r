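test_that("FWHM amplitude matches the analytic Gaussian oracle", {
  fs <- 500
  for (amp in c(2, -2, 0.8)) {
    for (fwhm in c(16, 24, 40)) {
      sigma <- fwhm / 2.355
      wave <- gaussian_wave(amp, 250, fwhm, fs)
      win <- list(t_start_ms = 150, t_end_ms = 350, polarity = sign(amp))
      m <- fwhm_amplitude(wave, fs, win)
      # discrete oracle: average the sampled Gaussian over the samples at or
      # above half-maximum (independent of the extractor's window logic)
      t <- (seq_along(wave) - 1) / fs * 1000
      oracle_d <- mean(wave[abs(wave) >= abs(amp) / 2 &
                              abs(t - 250) < 3 * fwhm])
      expect_equal(m$amplitude, oracle_d, tolerance = 1e-12)
      # continuous oracle: numeric integration over the analytic FWHM;
      # sample quantisation of the span biases the mean slightly upward
      half_w <- sigma * sqrt(2 * log(2))
      oracle <- stats::integrate(function(x) exp(-x^2 / (2 * sigma^2)),
                                 -half_w, half_w)$value / (2 * half_w) * amp
      expect_equal(m$t_peak_ms, 250, tolerance = 1.01 * 1000 / fs)
      # span within one sample of 2.355 sigma
      expect_lt(abs(diff(m$span_ms) - 2.355 * sigma), 2.01 * 1000 / fs)
      expect_lt(abs(m$amplitude - oracle), 0.07 * abs(oracle))
      expect_equal(sign(m$amplitude), sign(amp))
      expect_false(m$fallback)
    }
  }
})

test_that("FWHM of a rectangular pulse is its height over its full width", {
  fs <- 500
  wave <- numeric(250)
  wave[101:130] <- 3 # 60 ms pulse
  win <- list(t_start_ms = 100, t_end_ms = 350, polarity = 1)
  m <- fwhm_amplitude(wave, fs, win)
  expect_equal(m$amplitude, 3)
  expect_equal(diff(m$span_ms), 58) # 30 samples span
})

test_that("FWHM measurement is exactly homogeneous of degree one", {
  fs <- 500
  set.seed(3)
  wave <- gaussian_wave(-2, 175, 16, fs) + gaussian_wave(2, 200, 16, fs) +
    rnorm(250, sd = 0.05)
  win <- list(t_start_ms = 150, t_end_ms = 188, polarity = -1)
  m1 <- fwhm_amplitude(wave, fs, win)
  for (c in c(0.5, 2, 7.3)) {
    mc <- fwhm_amplitude(c * wave, fs, win)
    expect_equal(mc$amplitude, c * m1$amplitude, tolerance = 1e-12)
    expect_equal(mc$span_ms, m1$span_ms)
  }
})

test_that("a collapsed span falls back to the peak sample and is flagged", {
  fs <- 500
  wave <- numeric(100)
  wave[50] <- 5 # single-sample spike
  m <- fwhm_amplitude(wave, fs, list(t_start_ms = 80, t_end_ms = 120,
                                     polarity = 1))
  expect_true(m$fallback)
  expect_equal(m$amplitude, 5)
})

test_that("peak windows recover the four note-interval peaks", {
  cfg <- kernel_config()
  g <- kernel_wave(cfg$peaks, cfg$osc, 500, c(0, 500))
  w <- noteERP:::steady_epoch(g, g, 500, 4,
                              filters = noteERP:::calib_filters(500))
  wins <- find_peak_windows(w, 500, t0_ms = -250)
  first4 <- wins[wins$t_peak_ms < 250, ]
  expect_equal(nrow(first4), 4)
  expect_equal(first4$polarity, c(1, 1, -1, 1))
  for (k in 1:4) {
    target <- c(20, 100, 175, 200)[k]
    expect_true(first4$t_start_ms[k] <= target &&
                  first4$t_end_ms[k] >= target)
    expect_lt(abs(first4$t_peak_ms[k] - target), 10)
  }
  # windows ordered and non-overlapping
  expect_true(all(diff(as.vector(rbind(wins$t_start_ms, wins$t_end_ms))) >= 0))
})

test_that("deviant-minus-standard windows cover the mismatch and late peaks", {
  cfg <- kernel_config()
  prof <- mean_profile()
  ks <- condition_kernels(prof, cfg, block_s = 60)
  diffw <- noteERP:::steady_epoch(ks$deviant, ks$standard, 500, 4,
                                  filters = noteERP:::calib_filters(500)) -
    noteERP:::steady_epoch(ks$standard, ks$standard, 500, 4,
                           filters = noteERP:::calib_filters(500))
  wins <- find_peak_windows(diffw, 500, t0_ms = -250)
  covers <- function(tt) any(wins$t_start_ms <= tt & wins$t_end_ms >= tt)
  expect_true(covers(175))
  expect_true(covers(300))
})

test_that("window detection is stable under 1% noise", {
  cfg <- kernel_config()
  g <- kernel_wave(cfg$peaks, cfg$osc, 500, c(0, 500))
  w <- noteERP:::steady_epoch(g, g, 500, 4)
  ref <- find_peak_windows(w, 500, t0_ms = -250)
  ref <- ref[ref$t_peak_ms < 250, ]
  set.seed(11)
  for (rep in 1:10) {
    noisy <- w + rnorm(length(w), sd = 0.01 * max(abs(w)))
    wn <- find_peak_windows(noisy, 500, t0_ms = -250)
    wn <- wn[wn$t_peak_ms < 250, ]
    expect_equal(nrow(wn), 4)
    expect_true(all(abs(wn$t_start_ms - ref$t_start_ms) <= 4.01))
    expect_true(all(abs(wn$t_end_ms - ref$t_end_ms) <= 4.01))
  }
})

test_that("monotone input raises a no-peak error", {
  expect_error(find_peak_windows(seq(0, 0.4, length.out = 250), 500,
                                 t0_ms = 0),
               "no peaks")
})

test_that("electrode selection follows the gain map and ignores labels", {
  fs <- 500
  layout <- channel_layout()
  g <- kernel_wave(kernel_config()$peaks, NULL, fs, c(0, 500))
  mk <- function(scale) outer(layout$gain * scale, g)
  grands <- list(a = mk(1), b = mk(1.5))
  expect_equal(select_electrode(grands, layout, fs, 0), "Fz")
  # permuting condition labels cannot change the choice
  expect_equal(select_electrode(rev(grands), layout, fs, 0), "Fz")
  # a layout peaking at Cz selects Cz
  lay2 <- layout
  lay2$gain[lay2$label == "Cz"] <- 1.2
  grands2 <- list(outer(lay2$gain, g))
  expect_equal(select_electrode(grands2, lay2, fs, 0), "Cz")
  # mastoids never win, even with an artifact on them
  lay3 <- layout
  m <- outer(lay3$gain, g)
  m[lay3$label == "M1", ] <- 50
  expect_false(select_electrode(list(m), lay3, fs, 0) %in% c("M1", "M2"))
})
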