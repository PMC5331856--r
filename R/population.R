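#' Default condition-effect configuration
#'
#' Mean percent modulations (on the measured, mean-free FWHM amplitude
#' scale; see [condition_kernels()]), their between-subject standard
#' deviations, and the latent-factor correlation targets that couple the
#' pattern/random contrasts to the oddball responses and to self-reported
#' scale familiarity.
#'
#' * `mod_n175` -56.42: the ~175 ms negative peak goes further negative for
#'   random than for patterned notes.
#' * `mod_p200` +45.41: the ~200 ms positive peak increases for random notes.
#' * `mod_mmn` -300.35: the rare note's ~175 ms response is reduced (more
#'   negative; mismatch negativity) relative to the frequent note.
#' * `mod_p300` +759.77: the rare note's ~300 ms response increases (P300).
#' * `rho_n175` 0.65: target across-subject Pearson correlation between the
#'   pattern-minus-random N175 amplitude difference and the rare-note
#'   ~175 ms amplitude.
#' * `rho_p200` 0.38: ditto for the ~200 ms difference and the ~300 ms
#'   rare-note amplitude.
#' * `rho_fam` -0.45: target correlation between the N175 difference and the
#'   1--7 familiarity rating (attenuated slightly by integer rounding).
#'
#' @return Named list of effect parameters.
#' @export
default_effects <- function() {
  list(
    mod_n175 = -56.42, mod_p200 = 45.41,
    mod_mmn = -300.35, mod_p300 = 759.77,
    sd_n175 = 5, sd_p200 = 5, sd_mmn = 15, sd_p300 = 40,
    rho_n175 = 0.65, rho_p200 = 0.38, rho_fam = -0.45,
    fam_mean = 4, fam_sd = 1.8
  )
}

#' Draw a population of subject profiles
#'
#' Each subject gets a latent standard-normal "sensitivity" `z` and four
#' percent-modulation parameters whose loadings on `z` are chosen so the
#' implied across-subject correlations hit the configured targets:
#' with loadings `-sqrt(rho)` on the pattern/random modulations and
#' `+sqrt(rho)` on the oddball modulations, the pattern-minus-random
#' amplitude *difference* (which flips the sign again) correlates `+rho`
#' with the oddball amplitude.  Familiarity ratings load on `z` with
#' `rho_fam / sqrt(rho_n175)` and are rounded to integers in 1..7.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effects Effect configuration, see [default_effects()].
#' @param seed Integer seed; profiles are fully reproducible.
#' @param noise_scale Per-subject EEG noise RMS in microvolts (default 5).
#' @return Data frame (one row per subject): `subject_id`, `z`, `mod_n175`,
#'   `mod_p200`, `mod_mmn`, `mod_p300`, `noise_scale`, `familiarity`.
#' @export
make_population <- function(n_subjects, effects = default_effects(),
                            seed = 1L, noise_scale = 5) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  for (rho in c(effects$rho_n175, effects$rho_p200)) {
    if (rho <= -1 || rho >= 1) stop("latent correlations must lie in (-1, 1)")
  }
  lam1 <- sqrt(abs(effects$rho_n175)) * sign(effects$rho_n175)
  lam2 <- sqrt(abs(effects$rho_p200)) * sign(effects$rho_p200)
  lam_f <- if (lam1 != 0) effects$rho_fam / lam1 else 0
  if (abs(lam_f) > 1) stop("rho_fam incompatible with rho_n175 (loading > 1)")
  with_local_seed(seed, {
    z <- stats::rnorm(n_subjects)
    mix <- function(lam) lam * z + sqrt(1 - lam^2) * stats::rnorm(n_subjects)
    u1 <- mix(-lam1) # pattern/random channels load negatively ...
    u2 <- mix(-lam2)
    v1 <- mix(lam1) # ... oddball channels positively (see Details)
    v2 <- mix(lam2)
    fam_raw <- effects$fam_mean + effects$fam_sd * mix(lam_f)
    data.frame(
      subject_id = seq_len(n_subjects),
      z = z,
      mod_n175 = effects$mod_n175 + effects$sd_n175 * u1,
      mod_p200 = effects$mod_p200 + effects$sd_p200 * u2,
      mod_mmn = effects$mod_mmn + effects$sd_mmn * v1,
      mod_p300 = effects$mod_p300 + effects$sd_p300 * v2,
      noise_scale = noise_scale,
      familiarity = pmin(7L, pmax(1L, as.integer(round(fam_raw))))
    )
  })
}
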