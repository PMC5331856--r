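#' Locate peak windows in a group-average waveform
#'
#' Local extrema exceeding an absolute prominence threshold become peaks
#' (maxima above `+min_prominence`, minima below `-min_prominence`).  Each
#' peak's window runs to the neighbouring zero crossings; where two
#' neighbouring peaks share a sign (no crossing between them) the boundary
#' is the midpoint between the extrema, which stays put when noise wiggles
#' the flat stretch between peaks.  Same-sign extrema closer than
#' `min_sep_ms` are merged, keeping the larger.
#'
#' @param wave Numeric waveform (single channel).
#' @param fs Sampling rate in Hz.
#' @param t0_ms Time of the first sample in ms (e.g. -250 for an epoch).
#' @param search_ms Two-element window searched for peaks (default 0--500).
#' @param min_prominence Minimum absolute peak amplitude, same units as
#'   `wave` (default 0.5).
#' @param min_sep_ms Merge radius for same-sign extrema (default 20).
#' @return Data frame with columns `peak_id`, `polarity` (+1/-1),
#'   `t_start_ms`, `t_end_ms`, `t_peak_ms`; ordered, non-overlapping.
#'   Errors if no peak exceeds the threshold.
#' @export
find_peak_windows <- function(wave, fs, t0_ms = 0, search_ms = c(0, 500),
                              min_prominence = 0.5, min_sep_ms = 20) {
  if (!length(wave)) stop("`wave` is empty")
  t_ms <- t0_ms + (seq_along(wave) - 1) / fs * 1000
  sel <- which(t_ms >= search_ms[1] & t_ms <= search_ms[2])
  w <- wave[sel]
  n <- length(w)
  if (n < 3) stop("search window too short")
  # local extrema (plateau-safe: >= on the left, > on the right)
  i <- 2:(n - 1)
  is_max <- w[i] >= w[i - 1] & w[i] > w[i + 1] & w[i] > min_prominence
  is_min <- w[i] <= w[i - 1] & w[i] < w[i + 1] & w[i] < -min_prominence
  cand <- i[is_max | is_min]
  if (!length(cand)) stop("no peaks exceed the prominence threshold")
  # merge same-sign peaks closer than min_sep_ms, larger first
  keep <- integer(0)
  for (ci in cand[order(-abs(w[cand]))]) {
    close_same <- keep[abs(keep - ci) / fs * 1000 < min_sep_ms &
                         sign(w[keep]) == sign(w[ci])]
    if (!length(close_same)) keep <- c(keep, ci)
  }
  keep <- sort(keep)
  pol <- sign(w[keep])
  # boundaries between consecutive peaks
  inner <- integer(0)
  if (length(keep) > 1) {
    for (k in seq_len(length(keep) - 1)) {
      a <- keep[k]; b <- keep[k + 1]
      seg <- a:b
      if (pol[k] != pol[k + 1]) {
        cross <- seg[which(sign(w[seg]) != pol[k])[1]] # first sample past zero
        inner[k] <- if (is.na(cross)) (a + b) %/% 2L else cross - 1L
      } else {
        inner[k] <- (a + b) %/% 2L # midpoint between same-sign extrema
      }
    }
  }
  starts <- c(boundary_out(w, keep[1], pol[1], -1L), inner)
  ends <- c(inner, boundary_out(w, keep[length(keep)], pol[length(keep)], 1L))
  data.frame(
    peak_id = sprintf("pk%03d", round(t_ms[sel][keep])),
    polarity = pol,
    t_start_ms = t_ms[sel][starts],
    t_end_ms = t_ms[sel][ends],
    t_peak_ms = t_ms[sel][keep],
    stringsAsFactors = FALSE
  )
}

# outer window edge: walk from the peak until the sign flips (zero crossing)
# or the search range ends
boundary_out <- function(w, ipk, pol, dir) {
  j <- ipk
  lim <- if (dir < 0) 1L else length(w)
  while (j != lim && sign(w[j + dir]) == pol) j <- j + dir
  j
}

#' FWHM mean amplitude of a peak within a window
#'
#' Finds the extremum of the window's polarity, takes half its value
#' (relative to the 0 baseline of the mean-free filtered signal) as the
#' half-maximum level, expands the contiguous span around the peak where the
#' signal keeps the peak's sign and exceeds the half-maximum in magnitude,
#' and averages the amplitudes over that span.
#'
#' @param wave Numeric waveform (single channel).
#' @param fs Sampling rate in Hz.
#' @param window One row of [find_peak_windows()] output (or a list with
#'   `t_start_ms`, `t_end_ms`, `polarity`).
#' @param t0_ms Time of the first sample of `wave` in ms.
#' @return List with `t_peak_ms`, `span_ms` (lo, hi), `amplitude` (mean over
#'   the span), `n_span`, and `fallback` (TRUE when the span collapsed below
#'   2 samples and the peak sample value was reported instead).
#' @export
fwhm_amplitude <- function(wave, fs, window, t0_ms = 0) {
  t_ms <- t0_ms + (seq_along(wave) - 1) / fs * 1000
  sel <- which(t_ms >= window$t_start_ms & t_ms <= window$t_end_ms)
  if (!length(sel)) stop("window lies outside the waveform support")
  pol <- window$polarity
  w <- wave[sel]
  # prefer an interior local extremum of the window's polarity: a response
  # peaking inside the window, not activity leaking across its edges
  nw <- length(w)
  ipk <- if (nw >= 3) {
    i <- 2:(nw - 1)
    v <- pol * w
    cand <- i[v[i] >= v[i - 1] & v[i] > v[i + 1] & v[i] > 0]
    if (length(cand)) cand[which.max(v[cand])] else which.max(v)[1]
  } else {
    which.max(pol * w)[1] # ties break toward earlier latency
  }
  peak <- w[ipk]
  half <- peak / 2
  ok <- sign(w) == sign(peak) & abs(w) >= abs(half)
  lo <- ipk
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- ipk
  while (hi < length(w) && ok[hi + 1]) hi <- hi + 1
  n_span <- hi - lo + 1L
  if (n_span < 2L) {
    return(list(t_peak_ms = t_ms[sel][ipk],
                span_ms = c(t_ms[sel][ipk], t_ms[sel][ipk]),
                amplitude = peak, n_span = n_span, fallback = TRUE))
  }
  list(t_peak_ms = t_ms[sel][ipk],
       span_ms = c(t_ms[sel][lo], t_ms[sel][hi]),
       amplitude = mean(w[lo:hi]), n_span = n_span, fallback = FALSE)
}

#' Select the analysis electrode from condition grand averages
#'
#' The channel whose across-condition average waveform has the largest
#' absolute amplitude anywhere in the search window.  Averaging across
#' conditions first keeps the choice unbiased with respect to condition
#' differences; mastoids are excluded.  Ties break toward the lowest channel
#' index.
#'
#' @param grand_avgs List of channels x samples matrices, one per condition
#'   (equal weight per condition).
#' @param layout The [channel_layout()] (rows match matrix rows).
#' @param fs Sampling rate in Hz.
#' @param t0_ms Time of the first column in ms.
#' @param search_ms Window scored (default 0--500 ms).
#' @return Channel label (character scalar).
#' @export
select_electrode <- function(grand_avgs, layout, fs, t0_ms = 0,
                             search_ms = c(0, 500)) {
  stopifnot(length(grand_avgs) >= 1)
  avg <- Reduce(`+`, grand_avgs) / length(grand_avgs)
  t_ms <- t0_ms + (seq_len(ncol(avg)) - 1) / fs * 1000
  cols <- t_ms >= search_ms[1] & t_ms <= search_ms[2]
  score <- apply(abs(avg[, cols, drop = FALSE]), 1, max)
  score[layout$label %in% mastoid_labels(layout)] <- -Inf
  layout$label[which.max(score)]
}
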