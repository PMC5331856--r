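test_that("profiles hit the configured effect means and correlations", {
  eff <- default_effects()
  pop <- make_population(4000, eff, seed = 31)
  expect_equal(mean(pop$mod_n175), eff$mod_n175, tolerance = 0.5)
  expect_equal(mean(pop$mod_p200), eff$mod_p200, tolerance = 0.5)
  expect_equal(sd(pop$mod_mmn), eff$sd_mmn, tolerance = 1)
  # the pattern-minus-random difference is proportional to -mod, the oddball
  # amplitude to +mod, so the observable correlation is +rho
  expect_equal(cor(-pop$mod_n175, pop$mod_mmn), eff$rho_n175,
               tolerance = 0.06)
  expect_equal(cor(-pop$mod_p200, pop$mod_p300), eff$rho_p200,
               tolerance = 0.06)
  expect_true(all(pop$familiarity %in% 1:7))
  # rho = 0 decouples the channels
  eff0 <- eff
  eff0$rho_n175 <- 1e-9
  eff0$rho_fam <- 0
  pop0 <- make_population(4000, eff0, seed = 32)
  expect_lt(abs(cor(-pop0$mod_n175, pop0$mod_mmn)), 0.05)
  expect_identical(make_population(50, eff, seed = 7),
                   make_population(50, eff, seed = 7))
  eff_bad <- eff
  eff_bad$rho_n175 <- 1.2
  expect_error(make_population(10, eff_bad), "\\(-1, 1\\)")
  expect_error(make_population(1, eff), ">= 2")
})

test_that("pink noise is seeded, unit-RMS, and 1/f-shaped", {
  x <- pink_noise(2^14, alpha = 1, seed = 5)
  expect_identical(x, pink_noise(2^14, alpha = 1, seed = 5))
  expect_false(identical(x, pink_noise(2^14, alpha = 1, seed = 6)))
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-9)
  p <- Mod(fft(x))^2
  f <- seq_len(2^13) # one-sided bins
  lo <- mean(p[f > 8 & f < 40])
  hi <- mean(p[f > 800 & f < 4000])
  expect_gt(lo / hi, 20) # roughly two decades apart in f, ~1/f power
})

test_that("a zero-noise single event reproduces the kernel exactly", {
  prof <- null_profile()
  seqs <- stim_sequence(60L, "pattern", rate_hz = 4, block_id = "one")
  ks <- condition_kernels(prof)
  rec <- simulate_recording(seqs, prof, noise = list(alpha = 1, scale = 0),
                            seed = 1, kernels = ks)
  fz <- match("Fz", rec$layout$label)
  i0 <- rec$events$sample[1]
  expect_equal(rec$data[fz, i0:(i0 + 249)], ks$pattern, tolerance = 1e-12)
  # mastoid channels stay silent at zero noise
  expect_equal(max(abs(rec$data[match("M1", rec$layout$label), ])), 0)
})

test_that("zero-noise trains equal an independent superposition oracle", {
  prof <- mean_profile()
  sq <- build_oddball_block(n_events = 40, p_deviant = 0.10, seed = 4)
  ks <- condition_kernels(prof, block_s = 10)
  rec <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 0),
                            seed = 1, kernels = ks)
  # oracle: convolve per-condition impulse trains with the kernels
  n <- ncol(rec$data)
  oracle <- numeric(n)
  for (cond in c("standard", "deviant")) {
    imp <- numeric(n)
    imp[rec$events$sample[rec$events$code == cond]] <- 1
    oracle <- oracle + stats::convolve(imp, rev(ks[[cond]]), type = "open")[1:n]
  }
  fz <- match("Fz", rec$layout$label)
  expect_equal(rec$data[fz, ], oracle, tolerance = 1e-8)
  # every channel is the Fz waveform scaled by its gain
  cz <- match("Cz", rec$layout$label)
  expect_equal(rec$data[cz, ],
               rec$layout$gain[cz] * rec$data[fz, ], tolerance = 1e-10)
})

test_that("recordings are bit-identical under a repeated seed", {
  prof <- make_population(2, seed = 9)[1, ]
  sq <- build_pattern_block(duration_s = 10)
  ks <- condition_kernels(prof, block_s = 10)
  r1 <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 5),
                           seed = 77, kernels = ks)
  r2 <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 5),
                           seed = 77, kernels = ks)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 5),
                           seed = 78, kernels = ks)
  expect_false(identical(r3$data, r1$data))
})

test_that("packet loss marks seeded gaps and zero rate marks none", {
  prof <- null_profile()
  sq <- build_pattern_block(duration_s = 20)
  ks <- condition_kernels(prof, block_s = 20)
  r0 <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 0),
                           packet_loss = NULL, seed = 1, kernels = ks)
  expect_false(any(r0$lost))
  r1 <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 0),
                           packet_loss = list(rate = 30, mean_gap_ms = 40),
                           seed = 1, kernels = ks)
  expect_gt(sum(r1$lost), 0)
  expect_true(all(r1$data[, r1$lost] == 0))
  r1b <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 0),
                            packet_loss = list(rate = 30, mean_gap_ms = 40),
                            seed = 1, kernels = ks)
  expect_identical(r1$lost, r1b$lost)
})

test_that("the study object matches the block plan and yoked design", {
  cfg <- default_config("smoke")
  study <- simulate_study(cfg, seed = 3)
  expect_equal(nrow(study$profiles), cfg$simulator$n_subjects)
  expect_equal(nrow(study$sequences$pattern$events),
               cfg$stimulus$block_s * cfg$stimulus$rate_hz)
  # full design: 5 blocks, two of them repeats of the same event sequence
  cfg_full <- default_config("full")
  expect_equal(cfg_full$simulator$blocks,
               c("pattern1", "pattern2", "random1", "random2", "oddball"))
  study_full <- simulate_study(cfg_full, seed = 3)
  expect_equal(ncol(study_full$block_order), 5)
  for (s in 1:5) {
    expect_equal(sort(study_full$block_order[s, ]), 1:5)
  }
  # ground truth: one row per subject
  expect_equal(nrow(study_full$profiles), 13)
})

test_that("EEG containers round-trip through the directory format", {
  prof <- make_population(2, seed = 2)[1, ]
  sq <- build_oddball_block(n_events = 20, p_deviant = 0.10, seed = 1)
  ks <- condition_kernels(prof, block_s = 5)
  rec <- simulate_recording(sq, prof, noise = list(alpha = 1, scale = 2),
                            packet_loss = list(rate = 60, mean_gap_ms = 30),
                            seed = 5, kernels = ks)
  dir <- tempfile("eeg")
  write_eeg_dir(rec, dir)
  back <- read_eeg_dir(dir)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$layout$label, rec$layout$label)
  expect_equal(back$events$sample, rec$events$sample)
  expect_equal(back$events$code, rec$events$code)
  expect_identical(back$lost, rec$lost)
  expect_equal(back$data, rec$data, tolerance = 1e-6) # float32 round-trip
})
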