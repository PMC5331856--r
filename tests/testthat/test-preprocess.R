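make_rec <- function(data, fs = 500, layout = channel_layout(),
                     events = data.frame(sample = integer(),
                                         code = character()),
                     lost = NULL) {
  structure(list(data = data, fs = fs, layout = layout, events = events,
                 lost = lost, block_id = "test", subject_id = 1L),
            class = "eeg_recording")
}

test_that("the passband preserves an 8 Hz sinusoid within 1%", {
  fs <- 500
  layout <- channel_layout()
  t <- (0:(20 * fs - 1)) / fs
  s <- sin(2 * pi * 8 * t)
  data <- matrix(rep(s, nrow(layout)), nrow = nrow(layout), byrow = TRUE)
  data[match(c("M1", "M2"), layout$label), ] <- 0
  rec <- preprocess(make_rec(data, fs, layout))
  mid <- (5 * fs):(15 * fs)
  expect_equal(max(abs(rec$data[match("Fz", layout$label), mid])), 1,
               tolerance = 0.01)
})

test_that("stopband attenuation at 100 Hz beats the analytic Butterworth bound", {
  fs <- 500
  layout <- channel_layout()
  t <- (0:(20 * fs - 1)) / fs
  s <- sin(2 * pi * 100 * t)
  data <- matrix(rep(s, nrow(layout)), nrow = nrow(layout), byrow = TRUE)
  data[match(c("M1", "M2"), layout$label), ] <- 0
  rec <- preprocess(make_rec(data, fs, layout))
  mid <- (5 * fs):(15 * fs)
  # single-pass order-4 magnitude at 100 Hz with 50 Hz cutoff
  bound <- 1 / sqrt(1 + (100 / 50)^8)
  expect_lt(max(abs(rec$data[match("Fz", layout$label), mid])), bound)
})

test_that("mastoid re-referencing removes a common offset and shared drift", {
  fs <- 500
  layout <- channel_layout()
  n <- 10 * fs
  set.seed(1)
  base <- matrix(rnorm(nrow(layout) * n, sd = 1), nrow = nrow(layout))
  rec1 <- preprocess(make_rec(base, fs, layout))
  rec2 <- preprocess(make_rec(base + 42, fs, layout)) # common DC everywhere
  expect_equal(rec1$data, rec2$data, tolerance = 1e-6)
  expect_error(preprocess(make_rec(base, fs, layout), band = c(0.01, 300)),
               "sampling rate")
  lay_nomast <- layout[!layout$label %in% c("M1", "M2"), ]
  class(lay_nomast) <- class(layout)
  expect_error(preprocess(make_rec(base[1:22, ], fs, lay_nomast)),
               "mastoid")
})

test_that("epochs are 375 samples with edge events dropped", {
  fs <- 500
  layout <- channel_layout()
  n <- 6 * fs
  data <- matrix(0, nrow(layout), n)
  ev <- data.frame(sample = c(10L, as.integer(fs * c(1, 2, 3, 4)), n - 10L),
                   code = "pattern")
  es <- epoch_recording(make_rec(data, fs, layout, ev))
  expect_equal(dim(es$epochs)[3], 375)
  expect_equal(length(es$codes), 4) # first and last lack full windows
  expect_equal(es$n_dropped_edge, 2)
  expect_error(epoch_recording(make_rec(data, fs, layout)), "no events")
})

test_that("a single lost sample inside a window rejects exactly that epoch", {
  fs <- 500
  layout <- channel_layout()
  n <- 6 * fs
  lost <- rep(FALSE, n)
  ev <- data.frame(sample = as.integer(fs * c(1, 2, 3, 4)), code = "pattern")
  lost[ev$sample[2] + 50] <- TRUE # +100 ms into epoch 2
  es <- epoch_recording(make_rec(matrix(0, nrow(layout), n), fs, layout, ev,
                                 lost = lost))
  expect_equal(which(es$rejected), 2L)
  expect_equal(es$reason[2], "packet_loss")
  # no mask, no rejections
  es2 <- epoch_recording(make_rec(matrix(0, nrow(layout), n), fs, layout, ev))
  expect_false(any(es2$rejected))
})

test_that("amplitude and variance rejection flag constructed outliers", {
  fs <- 500
  layout <- channel_layout()
  n <- 12 * fs
  set.seed(8)
  data <- matrix(rnorm(nrow(layout) * n, sd = 5), nrow(layout), n)
  ev <- data.frame(sample = as.integer(fs * (1:10)), code = "pattern")
  rec <- make_rec(data, fs, layout, ev)
  # inject a 500 uV transient into epoch 4
  rec$data[3, ev$sample[4] + 20] <- 500
  es <- reject_epochs(epoch_recording(rec), abs_uv = 100, var_z = 3.5)
  expect_true(es$rejected[4])
  expect_equal(es$reason[4], "amplitude")
  expect_false(any(es$rejected[-4]))
  # clean zero-noise epochs survive untouched
  rec0 <- make_rec(matrix(1, nrow(layout), n), fs, layout, ev)
  rec0$data <- rec0$data + outer(layout$gain, sin(2 * pi * 8 * (1:n) / fs))
  es0 <- reject_epochs(epoch_recording(rec0))
  expect_false(any(es0$rejected))
})

test_that("averaging is the pointwise mean of retained trials", {
  fs <- 500
  layout <- channel_layout()
  n <- 8 * fs
  data <- matrix(0, nrow(layout), n)
  ev <- data.frame(sample = as.integer(fs * (1:6)), code = "pattern")
  rec <- make_rec(data, fs, layout, ev)
  # epochs alternating +x and -x cancel
  for (k in seq_len(6)) {
    rec$data[, ev$sample[k] + 0:10] <- (-1)^k * 3
  }
  es <- epoch_recording(rec)
  a <- average_erp(es, "pattern")
  expect_equal(a$n, 6)
  expect_equal(max(abs(a$avg)), 0)
  expect_error(average_erp(es, "deviant"), "no retained")
})
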