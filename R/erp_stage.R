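#' Preprocess, epoch, reject, and average every block of a study
#'
#' Runs the per-subject chain (detrend + band-pass + mastoid re-reference,
#' epoching, packet-loss/amplitude/variance rejection, condition averaging)
#' on each recording, combining repeated blocks of the same condition by
#' trial-count-weighted averaging.  Recordings are generated (or loaded)
#' one at a time, so memory stays at one block.
#'
#' @param study An `erp_study` from [simulate_study()], or any list with
#'   `profiles`, `blocks` and a `recording(subject, block)` function.
#' @param config Pipeline configuration (`study$config$pipeline` by
#'   default).
#' @param verbose Print one line per subject.
#' @return List with `subject_avgs` (per subject, per condition: `avg`
#'   channels x samples and `n`), `layout`, `fs`, `t0_ms`, and `log`
#'   (per-block rejection counts).
#' @export
process_study <- function(study, config = study$config$pipeline,
                          verbose = FALSE) {
  n_sub <- nrow(study$profiles)
  subject_avgs <- vector("list", n_sub)
  log <- list()
  layout <- NULL
  fs <- NULL
  for (s in seq_len(n_sub)) {
    acc <- list() # condition -> list(sum = avg * n, n)
    for (block in study$blocks) {
      rec <- study$recording(s, block)
      layout <- rec$layout
      fs <- rec$fs
      rec <- preprocess(rec, band = config$band, order = config$order)
      es <- epoch_recording(rec, window_ms = config$window_ms)
      es <- reject_epochs(es, abs_uv = config$abs_uv, var_z = config$var_z)
      log[[paste0("s", s, "_", block)]] <- data.frame(
        subject = s, block = block, n_epochs = length(es$codes),
        n_rejected = sum(es$rejected),
        frac_rejected = mean(es$rejected)
      )
      for (cond in unique(es$codes)) {
        a <- average_erp(es, cond)
        if (is.null(acc[[cond]])) {
          acc[[cond]] <- list(sum = a$avg * a$n, n = a$n)
        } else {
          acc[[cond]]$sum <- acc[[cond]]$sum + a$avg * a$n
          acc[[cond]]$n <- acc[[cond]]$n + a$n
        }
      }
    }
    subject_avgs[[s]] <- lapply(acc, function(x) {
      list(avg = x$sum / x$n, n = x$n)
    })
    if (verbose) {
      message("subject ", s, ": ",
              paste(names(acc), vapply(acc, `[[`, 0, "n"), collapse = ", "),
              " retained trials")
    }
  }
  list(subject_avgs = subject_avgs, layout = layout, fs = fs,
       t0_ms = config$window_ms[1], log = do.call(rbind, unname(log)))
}

#' Group-guided peak measurement for one stage
#'
#' Selects the analysis electrode from the across-condition grand average,
#' finds the group peak windows there, and extracts every subject's
#' per-condition FWHM-mean amplitude inside each window.  For the
#' pattern/random stage the windows kept are those whose group peak falls
#' inside the 0--250 ms interval of the current note (later windows repeat
#' the following note's early peaks); for the oddball stage the windows
#' nearest 175 and 300 ms are kept (labels `odd175`, `odd300`).
#'
#' @param processed Output of [process_study()].
#' @param stage `"pattern"` (conditions pattern/random) or `"oddball"`
#'   (standard/deviant).
#' @param config Pipeline configuration ([default_config()]`$pipeline`).
#' @return List with `measures` (one row per subject x condition x peak:
#'   `stage`, `subject`, `condition`, `peak`, `polarity`,
#'   `t_peak_group_ms`, `t_peak_ms`, `span_lo_ms`, `span_hi_ms`,
#'   `amplitude`, `fallback`), `electrode`, `windows`, `grand` (electrode
#'   grand-average waveform per condition).
#' @export
run_erp_stage <- function(processed, stage = c("pattern", "oddball"),
                          config = default_config()$pipeline) {
  stage <- match.arg(stage)
  conds <- if (stage == "pattern") c("pattern", "random")
           else c("standard", "deviant")
  subs <- processed$subject_avgs
  have <- vapply(subs, function(s) all(conds %in% names(s)), TRUE)
  if (!all(have)) {
    stop("subjects missing ", stage, " conditions: ",
         paste(which(!have), collapse = ", "))
  }
  fs <- processed$fs
  t0 <- processed$t0_ms
  grands <- lapply(conds, function(cond) {
    Reduce(`+`, lapply(subs, function(s) s[[cond]]$avg)) / length(subs)
  })
  names(grands) <- conds
  electrode <- select_electrode(grands, processed$layout, fs, t0,
                                search_ms = config$search_ms)
  chan <- match(electrode, processed$layout$label)
  group_wave <- Reduce(`+`, lapply(grands, function(g) g[chan, ])) /
    length(grands)
  wins <- find_peak_windows(group_wave, fs, t0_ms = t0,
                            search_ms = config$search_ms,
                            min_prominence = config$min_prominence,
                            min_sep_ms = config$min_sep_ms)
  if (stage == "pattern") {
    wins <- wins[wins$t_peak_ms >= 0 & wins$t_peak_ms < 250, , drop = FALSE]
    if (!nrow(wins)) stop("no group peak windows inside 0-250 ms")
    wins$peak <- paste0("peak", seq_len(nrow(wins)))
  } else {
    pick <- vapply(c(175, 300), function(tt) {
      d <- abs(wins$t_peak_ms - tt)
      if (min(d) > 60) stop("no oddball peak window within 60 ms of ",
                            tt, " ms")
      which.min(d)
    }, 0L)
    wins <- wins[pick, , drop = FALSE]
    wins$peak <- c("odd175", "odd300")
  }
  rows <- list()
  for (s in seq_along(subs)) {
    for (cond in conds) {
      wave <- subs[[s]][[cond]]$avg[chan, ]
      for (k in seq_len(nrow(wins))) {
        m <- fwhm_amplitude(wave, fs, wins[k, ], t0_ms = t0)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stage, subject = s, condition = cond,
          peak = wins$peak[k], polarity = wins$polarity[k],
          t_peak_group_ms = wins$t_peak_ms[k], t_peak_ms = m$t_peak_ms,
          span_lo_ms = m$span_ms[1], span_hi_ms = m$span_ms[2],
          amplitude = m$amplitude, fallback = m$fallback,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(measures = do.call(rbind, rows), electrode = electrode,
       windows = wins, grand = lapply(grands, function(g) g[chan, ]))
}

#' Run the planned-comparison roster on a measures table
#'
#' Assembles exactly ten tests: four paired t-tests (pattern vs random, one
#' per peak within the note interval), two paired t-tests (deviant vs
#' standard at the ~175 and ~300 ms oddball peaks), two Pearson correlations
#' linking the pattern-minus-random amplitude differences (at the negative
#' ~175 ms and positive ~200 ms peaks) to the rare-note amplitudes at ~175
#' and ~300 ms, and two Pearson correlations of those differences with the
#' 1--7 familiarity rating.  All ten p-values then pass through
#' Holm-Bonferroni; group-level percent modulations are attached to every
#' amplitude contrast.
#'
#' @param measures Measures table from [run_erp_stage()] (both stages bound
#'   together).
#' @param familiarity Integer vector of self-reported scale familiarity,
#'   one per subject.
#' @param alpha Familywise alpha (default 0.05).
#' @return Object of class `planned_report`: list with `tests` (label,
#'   family, statistic, df, p, percent_modulation, holm_threshold,
#'   significant), `holm` (the step-down table), `alpha`.
#' @export
run_planned_comparisons <- function(measures, familiarity, alpha = 0.05) {
  amp <- function(stage, cond, peak) {
    sel <- measures$stage == stage & measures$condition == cond &
      measures$peak == peak
    sub <- measures[sel, ]
    miss <- setdiff(unique(measures$subject), sub$subject)
    if (length(miss)) {
      stop("missing measures for stage=", stage, " condition=", cond,
           " peak=", peak, " subject(s) ", paste(miss, collapse = ","))
    }
    sub$amplitude[order(sub$subject)]
  }
  pat_peaks <- unique(measures$peak[measures$stage == "pattern"])
  pat_peaks <- pat_peaks[order(as.integer(sub("peak", "", pat_peaks)))]
  if (length(pat_peaks) != 4) {
    stop("expected 4 pattern-stage peaks, found ", length(pat_peaks))
  }
  n_sub <- length(unique(measures$subject))
  if (length(familiarity) != n_sub) {
    stop("`familiarity` must have one rating per subject")
  }
  tests <- list()
  pm <- numeric(0)
  for (pk in pat_peaks) {
    p_amp <- amp("pattern", "pattern", pk)
    r_amp <- amp("pattern", "random", pk)
    tests[[length(tests) + 1L]] <-
      paired_t(p_amp, r_amp, label = paste0("pattern_random_", pk))
    pm[length(tests)] <- percent_modulation(mean(r_amp), mean(p_amp))
  }
  for (pk in c("odd175", "odd300")) {
    s_amp <- amp("oddball", "standard", pk)
    d_amp <- amp("oddball", "deviant", pk)
    tests[[length(tests) + 1L]] <-
      paired_t(d_amp, s_amp, label = paste0("oddball_", pk))
    pm[length(tests)] <- percent_modulation(mean(d_amp), mean(s_amp))
  }
  # peak identities for the correlation tests: negative peak nearest 175,
  # positive peak nearest 200, from the group window latencies
  wpat <- unique(measures[measures$stage == "pattern",
                          c("peak", "polarity", "t_peak_group_ms")])
  nearest <- function(pol, target) {
    cand <- wpat[wpat$polarity == pol, ]
    if (!nrow(cand)) stop("no pattern-stage peak with polarity ", pol)
    cand$peak[which.min(abs(cand$t_peak_group_ms - target))]
  }
  pk_n175 <- nearest(-1, 175)
  pk_p200 <- nearest(1, 200)
  d175 <- amp("pattern", "pattern", pk_n175) - amp("pattern", "random", pk_n175)
  d200 <- amp("pattern", "pattern", pk_p200) - amp("pattern", "random", pk_p200)
  mmn <- amp("oddball", "deviant", "odd175")
  p300 <- amp("oddball", "deviant", "odd300")
  tests[[7]] <- pearson_r(d175, mmn, label = "corr_n175diff_mmn")
  tests[[8]] <- pearson_r(d200, p300, label = "corr_p200diff_p300")
  tests[[9]] <- pearson_r(d175, familiarity, label = "corr_n175diff_familiarity")
  tests[[10]] <- pearson_r(d200, familiarity, label = "corr_p200diff_familiarity")
  pm <- c(pm, rep(NA_real_, 4))
  labels <- vapply(tests, `[[`, "", "label")
  pvals <- vapply(tests, `[[`, 0, "p")
  holm <- holm_bonferroni(pvals, alpha = alpha, labels = labels)
  tab <- data.frame(
    label = labels,
    family = vapply(tests, `[[`, "", "family"),
    statistic = vapply(tests, `[[`, 0, "statistic"),
    df = as.integer(vapply(tests, function(t) as.numeric(t$df), 0)),
    p = pvals,
    percent_modulation = pm,
    stringsAsFactors = FALSE
  )
  tab$holm_threshold <- holm$threshold[match(tab$label, holm$label)]
  tab$significant <- holm$significant[match(tab$label, holm$label)]
  structure(list(tests = tab, holm = holm, alpha = alpha),
            class = "planned_report")
}

#' @export
print.planned_report <- function(x, ...) {
  cat("Planned comparisons (Holm-Bonferroni over", nrow(x$tests),
      "tests, alpha =", x$alpha, ")\n")
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf(" %-28s %s = %8.4f  df = %2d  p = %.6f%s%s\n",
                t$label[i], ifelse(t$family[i] == "pearson", "r", "t"),
                t$statistic[i], t$df[i], t$p[i],
                ifelse(is.na(t$percent_modulation[i]), "",
                       sprintf("  mod = %+.2f%%", t$percent_modulation[i])),
                ifelse(t$significant[i], "  *", "")))
  }
  invisible(x)
}

#' Simulate, analyse, and test a whole study in one call
#'
#' Convenience wrapper: [simulate_study()] then [process_study()], both ERP
#' stages, and [run_planned_comparisons()].
#'
#' @param config Study configuration ([default_config()]).
#' @param seed Master seed.
#' @param verbose Passed to [process_study()].
#' @return List with `study`, `measures`, `pattern` and `oddball` stage
#'   outputs, `report`, `modulations` (named group-level percent
#'   modulations: n175, p200, mmn, p300), `electrode`, `log`.
#' @export
analyze_study <- function(config = default_config(), seed = 1L,
                          verbose = FALSE) {
  study <- simulate_study(config, seed)
  processed <- process_study(study, config$pipeline, verbose = verbose)
  pat <- run_erp_stage(processed, "pattern", config$pipeline)
  odd <- run_erp_stage(processed, "oddball", config$pipeline)
  measures <- rbind(pat$measures, odd$measures)
  report <- run_planned_comparisons(measures, study$profiles$familiarity,
                                    alpha = config$stats$alpha)
  tt <- report$tests
  mods <- c(
    n175 = tt$percent_modulation[tt$label == paste0("pattern_random_",
      attr_peak(measures, -1, 175))],
    p200 = tt$percent_modulation[tt$label == paste0("pattern_random_",
      attr_peak(measures, 1, 200))],
    mmn = tt$percent_modulation[tt$label == "oddball_odd175"],
    p300 = tt$percent_modulation[tt$label == "oddball_odd300"]
  )
  list(study = study, measures = measures, pattern = pat, oddball = odd,
       report = report, modulations = mods,
       electrode = pat$electrode, log = processed$log)
}

# pattern-stage peak label with the given polarity nearest a target latency
attr_peak <- function(measures, pol, target) {
  w <- unique(measures[measures$stage == "pattern",
                       c("peak", "polarity", "t_peak_group_ms")])
  w <- w[w$polarity == pol, ]
  w$peak[which.min(abs(w$t_peak_group_ms - target))]
}
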