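# Shared fixtures, built in code.

# A neutral subject profile with exactly the configured mean effects.
mean_profile <- function(effects = default_effects()) {
  data.frame(subject_id = 1L, z = 0,
             mod_n175 = effects$mod_n175, mod_p200 = effects$mod_p200,
             mod_mmn = effects$mod_mmn, mod_p300 = effects$mod_p300,
             noise_scale = 0, familiarity = 4L)
}

# A profile with no condition effects at all.
null_profile <- function() {
  data.frame(subject_id = 1L, z = 0, mod_n175 = 0, mod_p200 = 0,
             mod_mmn = 0, mod_p300 = 0, noise_scale = 0, familiarity = 4L)
}

# Measures table drawn under the global null: every amplitude is an
# independent draw around its peak's typical value, so no planned test has
# anything to detect.  Used for type-I calibration of the roster.
null_measures <- function(n_subjects = 13) {
  grid <- rbind(
    expand.grid(stage = "pattern", condition = c("pattern", "random"),
                peak = paste0("peak", 1:4), stringsAsFactors = FALSE),
    expand.grid(stage = "oddball", condition = c("standard", "deviant"),
                peak = c("odd175", "odd300"), stringsAsFactors = FALSE)
  )
  lat <- c(peak1 = 20, peak2 = 100, peak3 = 175, peak4 = 200,
           odd175 = 175, odd300 = 300)
  pol <- c(peak1 = 1, peak2 = 1, peak3 = -1, peak4 = 1,
           odd175 = -1, odd300 = 1)
  base <- c(peak1 = 1, peak2 = 2, peak3 = -2, peak4 = 2,
            odd175 = -2, odd300 = 0.5)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(
      stage = grid$stage[i], subject = seq_len(n_subjects),
      condition = grid$condition[i], peak = grid$peak[i],
      polarity = pol[[grid$peak[i]]],
      t_peak_group_ms = lat[[grid$peak[i]]],
      t_peak_ms = lat[[grid$peak[i]]],
      span_lo_ms = lat[[grid$peak[i]]] - 8,
      span_hi_ms = lat[[grid$peak[i]]] + 8,
      amplitude = base[[grid$peak[i]]] + stats::rnorm(n_subjects, sd = 0.5),
      fallback = FALSE, stringsAsFactors = FALSE
    )
  }))
  out
}

# An isolated sampled Gaussian peak on a flat baseline.
gaussian_wave <- function(amp, center_ms, fwhm_ms, fs = 500, dur_ms = 500) {
  t <- (seq_len(round(dur_ms * fs / 1000)) - 1) / fs * 1000
  sigma <- fwhm_ms / 2.355
  amp * exp(-(t - center_ms)^2 / (2 * sigma^2))
}
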