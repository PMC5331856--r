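#' Injected-effect recovery run
#'
#' Simulates the 13-subject study at the low-noise recovery preset (one
#' patterned, one random, and one oddball block per subject) and reports
#' the group-level percent modulations the pipeline recovers for the four
#' injected contrasts, alongside the generator's configured means.
#'
#' @param seed Master seed.
#' @param config Configuration (default the `"recovery"` preset).
#' @return List with `recovered` (named vector: n175, p200, mmn, p300),
#'   `injected` (configured mean modulations), `electrode`, `report`, and
#'   the full `analysis` output.
#' @export
run_recovery_study <- function(seed = 1L,
                               config = default_config("recovery")) {
  out <- analyze_study(config, seed)
  eff <- config$simulator$effects
  list(
    recovered = out$modulations,
    injected = c(n175 = eff$mod_n175, p200 = eff$mod_p200,
                 mmn = eff$mod_mmn, p300 = eff$mod_p300),
    electrode = out$electrode,
    report = out$report,
    analysis = out
  )
}

#' Latent-correlation recovery run
#'
#' Simulates a large population (default 500 subjects) with short low-noise
#' blocks, runs the full pipeline, and computes the across-subject Pearson
#' correlation between the N175 pattern-minus-random amplitude difference
#' and the rare-note ~175 ms (mismatch) amplitude -- the quantity whose
#' population value is set by the generator's `rho_n175`.
#'
#' @param n_subjects Population size (default 500).
#' @param seed Master seed.
#' @param block_s Block duration in seconds (default 20; short blocks keep
#'   a 500-subject run tractable while leaving measurement noise well below
#'   the between-subject effect spread).
#' @param config Base configuration (default the `"recovery"` preset).
#' @return List with `r` (empirical Pearson r), `rho_target`, `n`,
#'   `test` (the full `test_result`), and `electrode`.
#' @export
run_correlation_study <- function(n_subjects = 500L, seed = 1L,
                                  block_s = 20,
                                  config = default_config("recovery")) {
  config$simulator$n_subjects <- as.integer(n_subjects)
  config$stimulus$block_s <- block_s
  study <- simulate_study(config, seed)
  processed <- process_study(study, config$pipeline)
  pat <- run_erp_stage(processed, "pattern", config$pipeline)
  odd <- run_erp_stage(processed, "oddball", config$pipeline)
  m <- rbind(pat$measures, odd$measures)
  pk_n175 <- attr_peak(m, -1, 175)
  grab <- function(stage, cond, pk) {
    s <- m[m$stage == stage & m$condition == cond & m$peak == pk, ]
    s$amplitude[order(s$subject)]
  }
  d175 <- grab("pattern", "pattern", pk_n175) -
    grab("pattern", "random", pk_n175)
  mmn <- grab("oddball", "deviant", "odd175")
  ct <- pearson_r(d175, mmn, label = "corr_n175diff_mmn")
  list(r = ct$statistic, rho_target = config$simulator$effects$rho_n175,
       n = n_subjects, test = ct, electrode = pat$electrode)
}
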