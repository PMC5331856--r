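#' Construct a stimulus sequence
#'
#' The backbone container of the experiment: ordered note events on a rigid
#' onset grid.
#'
#' @param midi Integer MIDI pitches, one per event.
#' @param code Condition label per event; one of `"pattern"`, `"random"`,
#'   `"standard"`, `"deviant"`.
#' @param rate_hz Presentation rate; onsets are `(0:(n-1))/rate_hz` seconds.
#' @param block_id Block identifier string.
#' @return Object of class `stim_sequence`: list with `events` (data frame
#'   `onset_s`, `midi`, `name`, `code`), `rate_hz`, `block_id`.
#' @export
stim_sequence <- function(midi, code, rate_hz = 4, block_id = "block") {
  midi <- as.integer(midi)
  code <- as.character(code)
  stopifnot(length(midi) == length(code))
  bad <- setdiff(unique(code), c("pattern", "random", "standard", "deviant"))
  if (length(bad)) stop("illegal condition codes: ", paste(bad, collapse = ", "))
  n <- length(midi)
  structure(list(
    events = data.frame(
      onset_s = (seq_len(n) - 1L) / rate_hz,
      midi = midi,
      name = pitch_name(midi),
      code = code,
      stringsAsFactors = FALSE
    ),
    rate_hz = rate_hz,
    block_id = block_id
  ), class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence '%s': %d events at %g Hz (%g s), codes: %s>\n",
              x$block_id, nrow(x$events), x$rate_hz,
              nrow(x$events) / x$rate_hz,
              paste(unique(x$events$code), collapse = "/")))
  invisible(x)
}

#' Build a patterned (musical) stimulus block
#'
#' Notes run through the four scale shapes in order as overlapping sliding
#' windows; when the last shape finishes, the whole cycle repeats one
#' semitone higher.  Events are truncated at `duration_s * rate_hz`.
#'
#' @param start_key_pc Pitch class of the opening key (default 8, G#).
#' @param shapes List of [scale_shape()]s, default [default_shapes()] (E, D,
#'   C, A).
#' @param duration_s Block duration in seconds (default 300).
#' @param rate_hz Presentation rate in Hz (default 4).
#' @param start_anchor MIDI pitch of the opening key root (default 44, G#2).
#' @param window Sliding window length (default 3).
#' @param block_id Block label.
#' @return A [stim_sequence()] with all codes `"pattern"`.
#' @export
build_pattern_block <- function(start_key_pc = 8L, shapes = default_shapes(),
                                duration_s = 300, rate_hz = 4,
                                start_anchor = 44L, window = 3L,
                                block_id = "pattern") {
  n_events <- duration_s * rate_hz
  if (abs(n_events - round(n_events)) > 1e-9) {
    stop("duration_s * rate_hz must be an integer number of events")
  }
  n_events <- as.integer(round(n_events))
  if (as.integer(start_anchor) %% 12L != as.integer(start_key_pc)) {
    stop("`start_anchor` pitch class must match `start_key_pc`")
  }
  midi <- integer(0)
  anchor <- as.integer(start_anchor)
  while (length(midi) < n_events) {
    for (shape in shapes) {
      p <- shape_pitches(anchor %% 12L, shape, anchor)
      midi <- c(midi, sliding_window_pattern(p, window)$midi)
    }
    anchor <- anchor + 1L # next cycle: one semitone up
  }
  stim_sequence(midi[seq_len(n_events)], rep("pattern", n_events),
                rate_hz = rate_hz, block_id = block_id)
}

#' Build a random block by permuting a patterned block
#'
#' A seeded uniform permutation of the pattern block's notes on the same
#' onset grid, so the two conditions are physically identical as stimulus
#' multisets and differ only in order.
#'
#' @param pattern_seq A [stim_sequence()] to permute.
#' @param seed Integer seed; the same seed always yields the same order.
#' @param block_id Block label.
#' @return A [stim_sequence()] with all codes `"random"`.
#' @export
build_random_block <- function(pattern_seq, seed, block_id = "random") {
  stopifnot(inherits(pattern_seq, "stim_sequence"))
  n <- nrow(pattern_seq$events)
  if (n == 0L) stop("`pattern_seq` is empty")
  perm <- with_local_seed(seed, sample.int(n))
  stim_sequence(pattern_seq$events$midi[perm], rep("random", n),
                rate_hz = pattern_seq$rate_hz, block_id = block_id)
}

#' Build an oddball block
#'
#' A frequent standard note and a rare deviant note in seeded shuffled
#' order.  The deviant count is exact (`n_events * p_deviant`), not a
#' per-trial coin flip, reproducing fixed designs that report exact counts
#' (e.g. 120 deviants among 1200 events at p = 0.10).
#'
#' @param standard_midi MIDI pitch of the frequent note (default 43, G2 --
#'   the G on the thickest string).
#' @param deviant_midi MIDI pitch of the rare note (default 65, F4 -- the F
#'   at the first fret of the thinnest string).
#' @param p_deviant Deviant probability; `n_events * p_deviant` must be
#'   integral.
#' @param n_events Number of events (default 1200).
#' @param seed Integer seed for the shuffle.
#' @param rate_hz Presentation rate.
#' @param block_id Block label.
#' @return A [stim_sequence()] with codes `"standard"`/`"deviant"`.
#' @export
build_oddball_block <- function(standard_midi = 43L, deviant_midi = 65L,
                                p_deviant = 0.10, n_events = 1200L,
                                seed = 1L, rate_hz = 4,
                                block_id = "oddball") {
  if (p_deviant <= 0 || p_deviant >= 1) stop("`p_deviant` must be in (0, 1)")
  n_dev <- n_events * p_deviant
  if (abs(n_dev - round(n_dev)) > 1e-9) {
    stop("n_events * p_deviant must be an integer (got ", n_dev, ")")
  }
  n_dev <- as.integer(round(n_dev))
  code <- rep("standard", n_events)
  dev_at <- with_local_seed(seed, sample.int(n_events, n_dev))
  code[dev_at] <- "deviant"
  midi <- ifelse(code == "deviant", deviant_midi, standard_midi)
  stim_sequence(midi, code, rate_hz = rate_hz, block_id = block_id)
}

#' Latin-square block order for a subject
#'
#' Builds a seeded randomized 5 x 5 (in general `n_blocks` x `n_blocks`)
#' Latin square -- a cyclic square with rows, columns, and symbols permuted
#' under the seed -- and returns the row for the given subject.  Subjects
#' beyond the square reuse rows cyclically (`subject_index %% n_blocks`).
#'
#' @param n_blocks Number of blocks (default 5).
#' @param subject_index Zero-based subject index.
#' @param seed Integer seed shared by all subjects of a study.
#' @return Integer permutation of `1:n_blocks`.
#' @export
latin_square_order <- function(n_blocks = 5L, subject_index = 0L, seed = 1L) {
  if (subject_index < 0) stop("`subject_index` must be >= 0")
  n <- as.integer(n_blocks)
  sq <- with_local_seed(seed, {
    base <- outer(0:(n - 1L), 0:(n - 1L), function(i, j) (i + j) %% n) + 1L
    base <- base[sample.int(n), sample.int(n)]
    matrix(sample.int(n)[base], n, n)
  })
  sq[as.integer(subject_index) %% n + 1L, ]
}

#' Write a stimulus sequence as a tab-delimited event file
#'
#' Columns: `onset_s`, `onset_sample`, `pitch_midi`, `pitch_name`, `code`,
#' `block_id`; one header line, UTF-8, Unix newlines.
#'
#' @param seq A [stim_sequence()].
#' @param path Output path.
#' @param fs Sampling rate used to derive `onset_sample` (1-based).
#' @export
write_events <- function(seq, path, fs = 500) {
  ev <- seq$events
  out <- data.frame(
    onset_s = ev$onset_s,
    onset_sample = as.integer(round(ev$onset_s * fs)) + 1L,
    pitch_midi = ev$midi,
    pitch_name = ev$name,
    code = ev$code,
    block_id = seq$block_id,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(out, format_plain), list(sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}

format_plain <- function(x) {
  if (is.numeric(x) && !is.integer(x)) formatC(x, format = "fg", digits = 15)
  else as.character(x)
}

#' Read a tab-delimited event file back into a stimulus sequence
#'
#' @param path Path written by [write_events()].
#' @return A [stim_sequence()].
#' @export
read_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rate <- if (nrow(tab) > 1) 1 / diff(tab$onset_s[1:2]) else 4
  stim_sequence(tab$pitch_midi, tab$code, rate_hz = round(rate, 6),
                block_id = tab$block_id[1])
}
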