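#' Preprocess an EEG recording
#'
#' Per channel: linear detrend, then a zero-phase Butterworth band-pass
#' (applied forward and backward), then re-referencing to the mean of the
#' two mastoid channels.
#'
#' The band-pass is realised as a cascade of an order-`order` high-pass and
#' an order-`order` low-pass, each run through `signal::filtfilt()`.  A
#' single band-pass design with a 0.01 Hz lower edge at a 500 Hz sampling
#' rate places poles too close to the unit circle for a stable
#' transfer-function realisation; the cascade is numerically exact to well
#' under 2% in the passband.
#'
#' @param rec An `eeg_recording` (see [simulate_recording()] /
#'   [read_eeg_dir()]).
#' @param band Passband in Hz (default `c(0.01, 50)`).
#' @param order Butterworth order for each section (default 4).
#' @return The recording with filtered, re-referenced data.
#' @export
preprocess <- function(rec, band = c(0.01, 50), order = 4) {
  fs <- rec$fs
  if (fs <= 2 * band[2]) stop("sampling rate must exceed twice the upper cutoff")
  mast <- mastoid_labels(rec$layout)
  if (length(mast) < 2) stop("layout must contain mastoid channels M1 and M2")
  x <- t(rec$data) # samples x channels
  n <- nrow(x)
  tt <- seq_len(n) - (n + 1) / 2 # centered time index
  x <- sweep(x, 2, colMeans(x)) # linear detrend, all channels at once
  x <- x - tt %o% as.vector((tt %*% x) / sum(tt * tt))
  x <- apply_cascade(calib_filters(fs, band, order), x)
  x <- t(x)
  ref <- colMeans(x[match(mast, rec$layout$label), , drop = FALSE])
  x <- sweep(x, 2, ref)
  rec$data <- x
  rec$preprocessed <- list(band = band, order = order, reference = mast)
  rec
}

#' Cut stimulus-locked epochs from a recording
#'
#' One epoch per event with a full `[-250, 500)` ms window (half-open, the
#' sample at t = 0 included: 375 samples at 500 Hz).  Events whose window
#' would run off either end of the recording are dropped (counted in
#' `n_dropped_edge`).  Epochs overlapping any lost-packet sample are flagged
#' rejected with reason `packet_loss`.
#'
#' @param rec An `eeg_recording`.
#' @param window_ms Epoch window in ms relative to stimulus onset
#'   (default `c(-250, 500)`, half-open on the right).
#' @return An `epoch_set`: list with `epochs` (trials x channels x samples
#'   array), `fs`, `t0_ms`, `codes`, `rejected`, `reason`, `layout`,
#'   `n_dropped_edge`.
#' @export
epoch_recording <- function(rec, window_ms = c(-250, 500)) {
  fs <- rec$fs
  if (!nrow(rec$events)) stop("recording has no events")
  rel <- seq(round(window_ms[1] * fs / 1000),
             round(window_ms[2] * fs / 1000) - 1L)
  n <- ncol(rec$data)
  idx0 <- rec$events$sample
  full <- idx0 + rel[1] >= 1L & idx0 + rel[length(rel)] <= n
  n_dropped <- sum(!full)
  idx0 <- idx0[full]
  codes <- rec$events$code[full]
  if (!length(idx0)) stop("no events with a full epoch window")
  n_tr <- length(idx0)
  n_ch <- nrow(rec$data)
  epochs <- array(NA_real_, dim = c(n_tr, n_ch, length(rel)))
  lost <- rec$lost
  rejected <- logical(n_tr)
  reason <- character(n_tr)
  for (k in seq_len(n_tr)) {
    cols <- idx0[k] + rel
    epochs[k, , ] <- rec$data[, cols]
    if (!is.null(lost) && any(lost[cols])) {
      rejected[k] <- TRUE
      reason[k] <- "packet_loss"
    }
  }
  structure(list(epochs = epochs, fs = fs, t0_ms = window_ms[1],
                 codes = codes, rejected = rejected, reason = reason,
                 layout = rec$layout, n_dropped_edge = n_dropped),
            class = "epoch_set")
}

#' Flag artifactual epochs
#'
#' A threshold-based stand-in for toolbox artifact detection: an epoch is
#' rejected when any non-mastoid channel exceeds `abs_uv` in absolute
#' amplitude, or when its mean per-channel variance is more than `var_z`
#' standard deviations above the across-epoch mean.  Flags add to any
#' existing `packet_loss` flags.
#'
#' @param es An `epoch_set`.
#' @param abs_uv Absolute amplitude threshold in microvolts (default 100).
#' @param var_z Variance z-score threshold (default 3.5).
#' @return The `epoch_set` with updated `rejected`/`reason`.
#' @export
reject_epochs <- function(es, abs_uv = 100, var_z = 3.5) {
  if (sum(!es$rejected) < 2) stop("need at least 2 retained epochs")
  keep_ch <- !(es$layout$label %in% mastoid_labels(es$layout))
  sub <- es$epochs[, keep_ch, , drop = FALSE]
  nt <- dim(sub)[1]
  nc <- dim(sub)[2]
  ns <- dim(sub)[3]
  flat <- abs(matrix(sub, nrow = nt)) # trials x (channel, sample)
  amp_bad <- flat[cbind(seq_len(nt), max.col(flat, "first"))] > abs_uv
  tc <- matrix(sub, nrow = nt * nc) # (trial, channel) x sample
  v_tc <- (rowMeans(tc^2) - rowMeans(tc)^2) * ns / (ns - 1)
  v <- rowMeans(matrix(v_tc, nrow = nt))
  vz <- (v - mean(v)) / stats::sd(v)
  var_bad <- is.finite(vz) & vz > var_z
  add <- (amp_bad | var_bad) & !es$rejected
  es$reason[add] <- ifelse(amp_bad[add], "amplitude", "variance")
  es$rejected <- es$rejected | amp_bad | var_bad
  if (all(es$rejected)) {
    stop("all epochs rejected (", sum(amp_bad), " amplitude, ",
         sum(var_bad), " variance, ",
         sum(es$reason == "packet_loss"), " packet loss)")
  }
  es
}

#' Average retained epochs of one condition
#'
#' @param es An `epoch_set`.
#' @param condition Condition code to average.
#' @return List with `avg` (channels x samples matrix), `n` (trial count),
#'   `fs`, `t0_ms`.
#' @export
average_erp <- function(es, condition) {
  pick <- which(es$codes == condition & !es$rejected)
  if (!length(pick)) stop("no retained epochs with code '", condition, "'")
  avg <- colMeans(es$epochs[pick, , , drop = FALSE]) # channels x samples
  list(avg = avg, n = length(pick), fs = es$fs, t0_ms = es$t0_ms)
}
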