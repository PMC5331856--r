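#' Synthesize a single note
#'
#' Default method is a plucked-string delay-line model (a noise-filled
#' delay line of length `fs/f` averaged recursively, giving a decaying
#' harmonic tone); `"additive"` sums exponentially decaying harmonics.
#' Either way the waveform is mean-removed, linearly ramped over the first
#' and last 10 ms, and scaled so its maximum absolute amplitude is 0.40.
#'
#' @param frequency_hz Fundamental frequency; must be below Nyquist.
#' @param duration_s Note duration in seconds (default 0.250).
#' @param fs_audio Audio sampling rate in Hz (default 44100).
#' @param method `"pluck"` or `"additive"`.
#' @param ramp_s Attack/release ramp duration (default 0.010).
#' @param peak Target maximum absolute amplitude (default 0.40).
#' @return Numeric vector of `round(duration_s * fs_audio)` samples in
#'   \[-peak, peak\].
#' @export
synthesize_note <- function(frequency_hz, duration_s = 0.250,
                            fs_audio = 44100,
                            method = c("pluck", "additive"),
                            ramp_s = 0.010, peak = 0.40) {
  method <- match.arg(method)
  if (frequency_hz <= 0 || frequency_hz >= fs_audio / 2) {
    stop("`frequency_hz` must lie in (0, fs_audio/2)")
  }
  n <- as.integer(round(duration_s * fs_audio))
  x <- switch(method,
    pluck = pluck_wave(frequency_hz, n, fs_audio),
    additive = additive_wave(frequency_hz, n, fs_audio)
  )
  x <- x - mean(x)
  nr <- as.integer(round(ramp_s * fs_audio))
  if (nr > 1L) {
    ramp <- seq(0, 1, length.out = nr)
    x[1:nr] <- x[1:nr] * ramp
    x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
  }
  x * (peak / max(abs(x)))
}

# Plucked-string synthesis: delay line seeded with uniform noise (seed
# derived from the frequency so a given pitch always renders identically),
# updated in whole-period blocks by the two-tap averaging recursion.
pluck_wave <- function(freq, n, fs) {
  p <- max(2L, as.integer(round(fs / freq)))
  buf <- with_local_seed(seed_stream(77003L, "pluck", round(freq * 1000)),
                         stats::runif(p, -1, 1))
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    k <- min(p, n - i + 1L)
    buf <- 0.5 * (buf + c(buf[p], buf[-p]))
    out[i:(i + k - 1L)] <- buf[1:k]
    i <- i + k
  }
  out
}

additive_wave <- function(freq, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  kmax <- max(1L, min(6L, floor((fs / 2 - 1) / freq)))
  x <- numeric(n)
  for (k in seq_len(kmax)) {
    x <- x + (1 / k) * sin(2 * pi * k * freq * t) * exp(-t / 0.2)
  }
  x
}

#' Render a stimulus sequence to an audio waveform
#'
#' Each event's note fills its inter-onset slot exactly (no silence); the
#' per-pitch waveform is synthesized once and reused, so rendering is
#' deterministic.
#'
#' @param seq A [stim_sequence()].
#' @param fs_audio Audio sampling rate (default 44100).
#' @param method Synthesis method, see [synthesize_note()].
#' @return Numeric vector of `n_events / rate_hz * fs_audio` samples.
#' @export
render_sequence <- function(seq, fs_audio = 44100,
                            method = c("pluck", "additive")) {
  method <- match.arg(method)
  ev <- seq$events
  slot <- 1 / seq$rate_hz
  nslot <- as.integer(round(slot * fs_audio))
  cache <- new.env(parent = emptyenv())
  out <- numeric(nslot * nrow(ev))
  for (i in seq_len(nrow(ev))) {
    key <- as.character(ev$midi[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- synthesize_note(midi_to_freq(ev$midi[i]),
                                      duration_s = slot,
                                      fs_audio = fs_audio, method = method)
    }
    i0 <- as.integer(round(ev$onset_s[i] * fs_audio))
    out[(i0 + 1L):(i0 + nslot)] <- cache[[key]]
  }
  out
}

#' Amplitude-envelope power spectrum of an audio waveform
#'
#' Full-wave rectification followed by a zero-phase low-pass (4th-order
#' Butterworth, default cutoff 20 Hz), decimation, and a periodogram.
#' For a note train presented at a fixed rate the spectrum peaks at the
#' presentation rate with harmonics above it.
#'
#' @param audio Numeric waveform.
#' @param fs_audio Sampling rate of `audio`.
#' @param lp_hz Envelope low-pass cutoff (default 20).
#' @param fs_env Envelope sampling rate after decimation (default 200).
#' @return Data frame with columns `freq` (Hz) and `power`; frequency
#'   resolution is `fs_audio / length(audio)` (<= 0.1 Hz for >= 10 s input).
#' @export
envelope_spectrum <- function(audio, fs_audio = 44100, lp_hz = 20,
                              fs_env = 200) {
  if (length(audio) < 10 * fs_audio) {
    stop("`audio` must be at least 10 s long")
  }
  env <- abs(audio)
  if (stats::sd(env) > 0) {
    lp <- signal::butter(4, lp_hz / (fs_audio / 2), type = "low")
    env <- signal::filtfilt(lp, env)
  }
  dec <- max(1L, as.integer(floor(fs_audio / fs_env)))
  env <- env[seq(1L, length(env), by = dec)]
  fs_d <- fs_audio / dec
  env <- env - mean(env)
  n <- length(env)
  p <- Mod(stats::fft(env))^2 / n
  keep <- seq_len(floor(n / 2))
  data.frame(freq = (keep - 1) * fs_d / n, power = p[keep])
}

#' Frequency of the strongest envelope-spectrum peak
#'
#' @param spec Data frame from [envelope_spectrum()].
#' @param range Frequency band searched (default 1--20 Hz, excluding DC).
#' @return Frequency in Hz of the maximum power within `range`.
#' @export
envelope_peak <- function(spec, range = c(1, 20)) {
  sel <- spec$freq >= range[1] & spec$freq <= range[2]
  if (!any(sel)) stop("no spectral bins inside `range`")
  spec$freq[sel][which.max(spec$power[sel])]
}
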