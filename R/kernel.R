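#' Default evoked-kernel configuration
#'
#' The single-stimulus evoked response is modelled as a sum of
#' Gaussian-windowed peaks (sigma = width / 2.355, so `width_ms` is the
#' FWHM) plus a Hann-windowed 8 Hz cosine, over a 0--500 ms support.  The
#' pattern/random kernel carries four peaks near 20, 100, 175 (negative)
#' and 200 ms -- two periods of an 8 Hz oscillation per 250 ms stimulus.
#' The oddball standard adds a small late positivity near 300 ms, the
#' deviant's mismatch (~175 ms) and late positive (~300 ms) components are
#' obtained by scaling those of the standard.  Absolute amplitudes are
#' placeholders (figures in this literature are rarely tabulated in
#' microvolts); analyses here use relative condition contrasts only.
#'
#' @param fs Sampling rate in Hz (default 500).
#' @return List with `peaks` (data frame `id`, `latency_ms`, `amp`,
#'   `width_ms`), `late_pos`, `osc`, `support_ms`, `fs`.
#' @export
kernel_config <- function(fs = 500) {
  list(
    peaks = data.frame(
      id = c("p20", "p100", "n175", "p200"),
      latency_ms = c(20, 100, 175, 200),
      amp = c(1, 2, -2, 2),
      width_ms = c(16, 16, 16, 16),
      stringsAsFactors = FALSE
    ),
    late_pos = data.frame(id = "lp300", latency_ms = 300, amp = 0.5,
                          width_ms = 24, stringsAsFactors = FALSE),
    osc = list(freq_hz = 8, amp = 0.3, phase = 0, support_ms = c(0, 250)),
    support_ms = c(0, 500),
    fs = fs
  )
}

#' Evaluate a kernel (peak table + oscillation) on its support grid
#'
#' @param peaks Data frame of peaks (`latency_ms`, `amp`, `width_ms`).
#' @param osc Oscillation settings (`freq_hz`, `amp`, `phase`, `support_ms`) or
#'   NULL.
#' @param fs Sampling rate.
#' @param support_ms Kernel support (default 0--500 ms).
#' @return Numeric vector of `diff(support_ms) * fs / 1000` samples.
#' @export
kernel_wave <- function(peaks, osc = NULL, fs = 500, support_ms = c(0, 500)) {
  n <- round(diff(support_ms) * fs / 1000)
  t <- support_ms[1] + (seq_len(n) - 1) / fs * 1000
  w <- numeric(n)
  for (k in seq_len(nrow(peaks))) {
    sigma <- peaks$width_ms[k] / 2.355
    w <- w + peaks$amp[k] * exp(-(t - peaks$latency_ms[k])^2 / (2 * sigma^2))
  }
  if (!is.null(osc) && osc$amp != 0) {
    inwin <- t >= osc$support_ms[1] & t <= osc$support_ms[2]
    tau <- (t - osc$support_ms[1]) / diff(osc$support_ms)
    hann <- 0.5 * (1 - cos(2 * pi * tau))
    w <- w + ifelse(inwin, 1, 0) * hann *
      osc$amp * cos(2 * pi * osc$freq_hz * (t - osc$support_ms[1]) / 1000 +
                      osc$phase)
  }
  w
}

# Expected (noise-free) epoch waveform of a condition embedded in a 4 Hz
# train, as the pipeline sees it after detrending and zero-phase band-pass
# filtering.  The steady-state part is the periodised expected kernel train
# (neighbour mixture `g_nb`), mean-free up to the small DC residual left by
# detrending a padded finite block; the event's own deviation from the
# expected kernel enters as an isolated filtered transient at t = 0.
steady_epoch <- function(g_own, g_nb, fs, rate_hz = 4,
                         window_ms = c(-250, 500), filters = NULL,
                         block_s = Inf, pad_s = 1) {
  n_ep <- round(diff(window_ms) * fs / 1000)
  step <- round(fs / rate_hz) # samples per stimulus
  zero_at <- -round(window_ms[1] * fs / 1000) + 1L # epoch index of t = 0
  nk <- length(g_own)
  cyc <- g_nb[seq_len(step)] + g_nb[step + seq_len(step)]
  mu <- mean(cyc)
  # detrending removes the block mean including the silent padding, so a
  # fraction 2*pad/(block+2*pad) of the train DC survives in the epochs
  resid_dc <- if (is.finite(block_s)) {
    mu * (2 * pad_s) / (block_s + 2 * pad_s)
  } else 0
  cyc <- cyc - mu
  cyc_f <- filter_periodic(cyc, filters)
  w <- cyc_f[(seq_len(n_ep) - zero_at) %% step + 1L] + resid_dc
  d <- g_own - g_nb
  if (any(d != 0)) {
    d_f <- filter_transient(d, filters, fs)
    j <- zero_at + seq_along(d_f) - 1L - length(d) # d_f starts 500 ms early
    ok <- j >= 1L & j <= n_ep
    w[j[ok]] <- w[j[ok]] + d_f[ok]
  }
  w
}

# Zero-phase Butterworth cascade matching preprocess(), as second-order
# sections (see filters.R); NULL disables a side.
calib_filters <- function(fs, band = c(0.01, 50), order = 4) {
  list(
    hp = if (band[1] > 0) butter_sos(order, band[1] / (fs / 2), "high"),
    lp = if (band[2] < fs / 2) butter_sos(order, band[2] / (fs / 2), "low")
  )
}

# Steady-state response of the cascade to a periodic cycle: filter a tiled
# copy and keep a middle cycle (edge transients die off well inside).
filter_periodic <- function(cyc, filters, reps = 16L) {
  if (is.null(filters)) return(cyc)
  x <- apply_cascade(filters, rep(cyc, reps))
  L <- length(cyc)
  x[(reps %/% 2) * L + seq_len(L)]
}

# Filtered isolated transient, returned from one kernel-length before its
# onset (zero-phase filtering spreads energy backwards in time).
filter_transient <- function(d, filters, fs, pad_s = 3) {
  nk <- length(d)
  if (is.null(filters)) return(c(numeric(nk), d))
  np <- round(pad_s * fs)
  x <- apply_cascade(filters, c(numeric(np), d, numeric(np)))
  x[(np - nk + 1L):(np + nk)]
}

# Measure percent modulations (test vs ref) of a noise-free condition pair
# exactly the way the pipeline does: peak windows from the unweighted
# across-condition average, FWHM-mean amplitude per condition, windows
# matched to the requested latencies.
measure_steady_mods <- function(w_ref, w_test, fs, targets_ms,
                                window_ms = c(-250, 500),
                                min_prominence = 0.5, min_sep_ms = 20,
                                search_ms = c(0, 500)) {
  grand <- (w_ref + w_test) / 2
  wins <- find_peak_windows(grand, fs, t0_ms = window_ms[1],
                            search_ms = search_ms,
                            min_prominence = min_prominence,
                            min_sep_ms = min_sep_ms)
  out <- numeric(length(targets_ms))
  for (k in seq_along(targets_ms)) {
    d <- abs(wins$t_peak_ms - targets_ms[k])
    if (min(d) > 60) stop("no peak window within 60 ms of ", targets_ms[k], " ms")
    win <- wins[which.min(d), ]
    a_ref <- fwhm_amplitude(w_ref, fs, win, t0_ms = window_ms[1])$amplitude
    a_test <- fwhm_amplitude(w_test, fs, win, t0_ms = window_ms[1])$amplitude
    out[k] <- percent_modulation(a_test, a_ref)
  }
  out
}

# Chord-Newton iteration for the 2-parameter gain calibrations below: the
# residual is nearly linear in the gains, so one numerical Jacobian at the
# starting point is reused across iterations.  `tol` is in percent points,
# per component; the forward model has a small numerical noise floor (the
# sample-quantised FWHM span), so the best iterate is accepted if it lands
# within 10x tol.
newton_solve <- function(fun, x0, tol = 0.02, max_iter = 40) {
  tol <- rep_len(tol, length(x0))
  x <- x0
  r <- fun(x)
  if (all(abs(r) < tol)) return(x)
  J <- matrix(0, length(r), length(x))
  for (j in seq_along(x)) {
    h <- 1e-3 * max(1, abs(x[j]))
    xh <- x
    xh[j] <- xh[j] + h
    J[, j] <- (fun(xh) - r) / h
  }
  best_x <- x
  best_r <- r
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) stop("kernel gain calibration: singular Jacobian")
    # damp very large steps to stay on the branch of the same peak windows
    smax <- max(abs(step) / pmax(1, abs(x)))
    if (smax > 0.5) step <- step * (0.5 / smax)
    # step-halving line search: the forward model is piecewise smooth (peak
    # windows and FWHM spans are sample-quantised), so insist on progress
    for (half in 0:4) {
      x_new <- x - step * 2^(-half)
      r_new <- fun(x_new)
      if (max(abs(r_new) / tol) < max(abs(r) / tol)) break
    }
    x <- x_new
    r <- r_new
    if (all(abs(r) < tol)) return(x)
    if (max(abs(r) / tol) < max(abs(best_r) / tol)) {
      best_x <- x
      best_r <- r
    }
  }
  # a sample-quantisation cliff can make the exact target unattainable for
  # an extreme profile; accept the nearest achievable gains (the caller
  # reports the achieved modulations) unless the miss is substantial
  if (max(abs(best_r)) < 10) return(best_x)
  stop("kernel gain calibration did not converge (worst residual ",
       signif(max(abs(best_r)), 3), " percent points)")
}

#' Build a subject's condition kernels with calibrated effect gains
#'
#' Condition effects are specified as percent modulations *of the measured
#' response*: the percent change, test vs reference condition, of the
#' FWHM-mean amplitude the pipeline extracts from the mean-free steady-state
#' epoch average.  (An AC-coupled pipeline can only ever see amplitudes
#' relative to the block mean, so defining effects on that scale is what
#' makes them recoverable.)  The component gains of the random and deviant
#' kernels are found by Newton iteration against the package's own
#' noise-free forward measurement.
#'
#' @param profile One-row subject profile (see [make_population()]), or any
#'   list with `mod_n175`, `mod_p200`, `mod_mmn`, `mod_p300` in percent.
#' @param config A [kernel_config()].
#' @param p_deviant Deviant probability of the oddball block (default 0.10).
#' @param rate_hz Stimulation rate (default 4).
#' @param band,order Band-pass of the measurement pipeline, mirrored in the
#'   calibration forward model (defaults 0.01--50 Hz, order 4).
#' @param block_s,pad_s Block duration and silent padding, which set the
#'   small DC residual that detrending a padded block leaves in the epochs.
#' @param min_prominence,min_sep_ms Peak-window parameters, matching the
#'   pipeline defaults.
#' @return List of kernel waveforms at unit topographic gain:
#'   `pattern`, `random`, `standard`, `deviant`, plus `fs` and
#'   `achieved` (the measured modulations of the calibrated kernels).
#' @export
condition_kernels <- function(profile, config = kernel_config(),
                              p_deviant = 0.10, rate_hz = 4,
                              band = c(0.01, 50), order = 4,
                              block_s = Inf, pad_s = 1,
                              min_prominence = 0.5, min_sep_ms = 20) {
  fs <- config$fs
  filters <- calib_filters(fs, band, order)
  steady <- function(g_own, g_nb) {
    steady_epoch(g_own, g_nb, fs, rate_hz, filters = filters,
                 block_s = block_s, pad_s = pad_s)
  }
  base <- config$peaks
  g_pat <- kernel_wave(base, config$osc, fs, config$support_ms)
  w_pat <- steady(g_pat, g_pat)

  rand_wave <- function(x) {
    pk <- base
    pk$amp[pk$id == "n175"] <- x[1]
    pk$amp[pk$id == "p200"] <- x[2]
    kernel_wave(pk, config$osc, fs, config$support_ms)
  }
  target_pr <- c(profile$mod_n175, profile$mod_p200)
  amp0 <- c(base$amp[base$id == "n175"], base$amp[base$id == "p200"])
  x0 <- amp0 + target_pr / 100 * abs(amp0)
  fun_pr <- function(x) {
    g_r <- rand_wave(x)
    measure_steady_mods(w_pat, steady(g_r, g_r), fs,
                        targets_ms = c(175, 200),
                        min_prominence = min_prominence,
                        min_sep_ms = min_sep_ms) - target_pr
  }
  x_pr <- if (all(target_pr == 0)) amp0 else {
    newton_solve(fun_pr, x0, tol = pmax(0.02, 1e-4 * abs(target_pr)))
  }
  g_rnd <- rand_wave(x_pr)

  std_peaks <- rbind(base, config$late_pos)
  g_std <- kernel_wave(std_peaks, config$osc, fs, config$support_ms)
  dev_wave <- function(x) {
    pk <- std_peaks
    pk$amp[pk$id == "n175"] <- x[1]
    pk$amp[pk$id == "lp300"] <- x[2]
    kernel_wave(pk, config$osc, fs, config$support_ms)
  }
  target_ob <- c(profile$mod_mmn, profile$mod_p300)
  amp0 <- c(std_peaks$amp[std_peaks$id == "n175"],
            std_peaks$amp[std_peaks$id == "lp300"])
  x0 <- amp0 + target_ob / 100 * abs(amp0)
  fun_ob <- function(x) {
    g_d <- dev_wave(x)
    g_mix <- (1 - p_deviant) * g_std + p_deviant * g_d
    measure_steady_mods(steady(g_std, g_mix), steady(g_d, g_mix), fs,
                        targets_ms = c(175, 300),
                        min_prominence = min_prominence,
                        min_sep_ms = min_sep_ms) - target_ob
  }
  x_ob <- if (all(target_ob == 0)) amp0 else {
    newton_solve(fun_ob, x0, tol = pmax(0.02, 1e-4 * abs(target_ob)))
  }
  g_dev <- dev_wave(x_ob)

  list(pattern = g_pat, random = g_rnd, standard = g_std, deviant = g_dev,
       fs = fs,
       achieved = c(n175 = fun_pr(x_pr)[1] + target_pr[1],
                    p200 = fun_pr(x_pr)[2] + target_pr[2],
                    mmn = fun_ob(x_ob)[1] + target_ob[1],
                    p300 = fun_ob(x_ob)[2] + target_ob[2]))
}

#' Per-channel evoked kernel for one condition
#'
#' The calibrated unit-gain kernel of the requested condition scaled by each
#' channel's topographic gain (maximal at Fz, ~0 at the mastoids).
#'
#' @param code One of `"pattern"`, `"random"`, `"standard"`, `"deviant"`.
#' @param profile One-row subject profile.
#' @param layout A [channel_layout()].
#' @param config A [kernel_config()].
#' @param ... Passed to [condition_kernels()].
#' @return Channels x samples matrix (rows follow `layout$label`).
#' @export
evoked_kernel <- function(code, profile, layout = channel_layout(),
                          config = kernel_config(), ...) {
  code <- match.arg(code, c("pattern", "random", "standard", "deviant"))
  ks <- condition_kernels(profile, config, ...)
  outer(layout$gain, ks[[code]])
}
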