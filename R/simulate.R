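#' Seeded 1/f^alpha ("pink") noise
#'
#' Spectral-shaping synthesis: complex Gaussian spectrum scaled by
#' `f^(-alpha/2)` (DC removed), inverse transformed and normalised to unit
#' RMS.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (default 1).
#' @param seed Integer seed.
#' @return Numeric vector, mean ~0, RMS 1.
#' @export
pink_noise <- function(n, alpha = 1, seed = 1L) {
  nf <- n %/% 2L
  ph <- with_local_seed(seed, list(re = stats::rnorm(nf), im = stats::rnorm(nf)))
  f <- seq_len(nf)
  mag <- f^(-alpha / 2)
  spec <- complex(real = ph$re * mag, imaginary = ph$im * mag)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

#' Simulate a multichannel EEG recording of one stimulus block
#'
#' The subject's condition kernels (see [condition_kernels()]) are inserted
#' at every event onset -- overlapping kernels sum linearly -- scaled per
#' channel by the layout gain, on top of independent per-channel 1/f^alpha
#' noise.  Optionally, seeded packet-loss gaps zero the signal and are
#' marked in a boolean mask.
#'
#' @param seq A [stim_sequence()].
#' @param profile One-row subject profile ([make_population()]).
#' @param layout A [channel_layout()].
#' @param noise List with `alpha` (spectral exponent) and `scale` (RMS in
#'   microvolts); `scale = 0` gives a noise-free recording.
#' @param packet_loss NULL, or a list with `rate` (expected gaps per minute)
#'   and `mean_gap_ms`.
#' @param seed Integer seed for noise and packet loss.
#' @param fs EEG sampling rate (default 500).
#' @param pad_s Silent padding before the first and after the last event so
#'   every epoch window fits (default 1).
#' @param kernels Optional precomputed [condition_kernels()] result (they
#'   depend only on the profile, so reuse across a subject's blocks).
#' @param kernel_cfg A [kernel_config()] used when `kernels` is NULL.
#' @return An `eeg_recording`: list with `data` (channels x samples, uV),
#'   `fs`, `layout`, `events` (`sample`, `code`), `lost` (logical mask),
#'   `block_id`, `subject_id`.
#' @export
simulate_recording <- function(seq, profile, layout = channel_layout(),
                               noise = list(alpha = 1, scale = 5),
                               packet_loss = NULL, seed = 1L, fs = 500,
                               pad_s = 1, kernels = NULL,
                               kernel_cfg = kernel_config(fs)) {
  ev <- seq$events
  if (!nrow(ev)) stop("empty stimulus sequence")
  if (is.null(kernels)) {
    kernels <- condition_kernels(profile, kernel_cfg, rate_hz = seq$rate_hz,
                                 block_s = nrow(ev) / seq$rate_hz,
                                 pad_s = pad_s)
  }
  n_pad <- round(pad_s * fs)
  dur <- nrow(ev) / seq$rate_hz
  n <- as.integer(2L * n_pad + round(dur * fs))
  onset_smp <- n_pad + as.integer(round(ev$onset_s * fs)) + 1L
  train <- numeric(n)
  nk <- length(kernels$pattern)
  for (i in seq_len(nrow(ev))) {
    g <- kernels[[ev$code[i]]]
    j <- onset_smp[i] + seq_len(nk) - 1L
    ok <- j <= n
    train[j[ok]] <- train[j[ok]] + g[ok]
  }
  data <- outer(layout$gain, train)
  if (noise$scale > 0) {
    for (ch in seq_len(nrow(data))) {
      data[ch, ] <- data[ch, ] + noise$scale *
        pink_noise(n, noise$alpha, seed_stream(seed, "noise", ch))
    }
  }
  lost <- rep(FALSE, n)
  if (!is.null(packet_loss) && packet_loss$rate > 0) {
    lost <- with_local_seed(seed_stream(seed, "packets"), {
      n_gaps <- stats::rpois(1, packet_loss$rate * (n / fs) / 60)
      m <- rep(FALSE, n)
      if (n_gaps > 0) {
        starts <- sample.int(n, n_gaps)
        lens <- 1L + stats::rgeom(n_gaps,
                                  1 / max(1, packet_loss$mean_gap_ms * fs / 1000))
        for (k in seq_len(n_gaps)) {
          m[starts[k]:min(n, starts[k] + lens[k] - 1L)] <- TRUE
        }
      }
      m
    })
    data[, lost] <- 0
  }
  structure(list(data = data, fs = fs, layout = layout,
                 events = data.frame(sample = onset_smp, code = ev$code,
                                     stringsAsFactors = FALSE),
                 lost = lost, block_id = seq$block_id,
                 subject_id = profile$subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s': %d ch x %d samples @ %g Hz, %d events, %d lost samples>\n",
              x$block_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$events), sum(x$lost)))
  invisible(x)
}

#' Simulate a full multi-subject study
#'
#' Builds the shared stimulus sequences (the patterned sequence is identical
#' across its two blocks and all subjects; the random permutation and the
#' oddball order are fixed across subjects, as in a yoked design), draws the
#' subject population, assigns each subject a Latin-square block order, and
#' returns a lazy study object: recordings are generated on demand by
#' `study$recording(subject, block)` so a full-scale study never needs to be
#' held in memory.
#'
#' @param config Study configuration, see [default_config()].
#' @param seed Master integer seed; all stage seeds are derived substreams.
#' @return A `study` object: list with `profiles` (the ground-truth table),
#'   `sequences` (named list), `blocks` (block names in canonical order),
#'   `block_order` (subjects x blocks matrix of indices into `blocks`),
#'   `config`, `seed`, and `recording(subject, block_name)`.
#' @export
simulate_study <- function(config = default_config(), seed = 1L) {
  st <- config$stimulus
  sim <- config$simulator
  pat <- build_pattern_block(st$start_key_pc, default_shapes(), st$block_s,
                             st$rate_hz, st$start_anchor, st$window,
                             block_id = "pattern")
  rnd <- build_random_block(pat, seed_stream(seed, "random-order"),
                            block_id = "random")
  n_ev <- nrow(pat$events)
  odd <- build_oddball_block(st$standard_midi, st$deviant_midi, st$p_deviant,
                             n_ev, seed_stream(seed, "oddball-order"),
                             st$rate_hz, block_id = "oddball")
  blocks <- sim$blocks
  seq_of <- function(block) switch(sub("[0-9]+$", "", block),
                                   pattern = pat, random = rnd, oddball = odd)
  profiles <- make_population(sim$n_subjects, sim$effects,
                              seed_stream(seed, "subjects"),
                              noise_scale = sim$noise$scale)
  block_order <- t(vapply(seq_len(sim$n_subjects) - 1L, function(s) {
    latin_square_order(length(blocks), s, seed_stream(seed, "order"))
  }, integer(length(blocks))))
  kcache <- new.env(parent = emptyenv())
  recording <- function(subject, block) {
    if (!block %in% blocks) stop("unknown block '", block, "'")
    prof <- profiles[subject, ]
    key <- as.character(subject)
    if (is.null(kcache[[key]])) {
      pl <- config$pipeline
      kcache[[key]] <- condition_kernels(prof, sim$kernel,
                                         p_deviant = st$p_deviant,
                                         rate_hz = st$rate_hz,
                                         band = pl$band, order = pl$order,
                                         block_s = st$block_s,
                                         min_prominence = pl$min_prominence,
                                         min_sep_ms = pl$min_sep_ms)
    }
    simulate_recording(seq_of(block), prof, sim$layout,
                       noise = sim$noise, packet_loss = sim$packet_loss,
                       seed = seed_stream(seed, paste0("rec-", block), subject),
                       fs = sim$fs, kernels = kcache[[key]],
                       kernel_cfg = sim$kernel)
  }
  structure(list(profiles = profiles,
                 sequences = list(pattern = pat, random = rnd, oddball = odd),
                 blocks = blocks, block_order = block_order,
                 config = config, seed = seed, recording = recording),
            class = "erp_study")
}
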