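#' Pitch-class names in twelve-tone equal temperament
#'
#' Sharps-only spelling, indexed 0 (C) to 11 (B).
#' @keywords internal
PC_NAMES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

#' Semitone offsets of the diatonic major scale (W-W-H-W-W-W-H)
#' @keywords internal
MAJOR_STEPS <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

# MIDI range of a standard-tuned six-string guitar: E2 (open low E) to E6
# (high E string, 24th fret).
GUITAR_RANGE <- c(40L, 88L)

#' Convert a MIDI pitch to frequency
#'
#' Twelve-tone equal temperament with A4 = 440 Hz (MIDI 69):
#' \eqn{f = 440 \cdot 2^{(m - 69)/12}}.
#'
#' @param midi Integer MIDI pitch (A4 = 69).
#' @return Frequency in Hz.
#' @export
#' @examples
#' midi_to_freq(69) # 440
#' midi_to_freq(43) # G2, ~98 Hz
midi_to_freq <- function(midi) {
  440 * 2^((midi - 69) / 12)
}

#' Name a MIDI pitch
#'
#' @param midi Integer MIDI pitch.
#' @return Character label such as `"G#3"` (octave convention: C4 = MIDI 60).
#' @export
pitch_name <- function(midi) {
  midi <- as.integer(midi)
  paste0(PC_NAMES[midi %% 12L + 1L], midi %/% 12L - 1L)
}

#' Pitch classes of a major scale
#'
#' @param root_pc Root pitch class, integer in 0--11 (0 = C).
#' @return Integer vector of the 7 scale pitch classes, root first.
#' @export
#' @examples
#' major_scale(8) # G# major: G#, A#, C, C#, D#, F, G
major_scale <- function(root_pc) {
  if (length(root_pc) != 1L || is.na(root_pc) || root_pc < 0 || root_pc > 11 ||
      root_pc != as.integer(root_pc)) {
    stop("`root_pc` must be a single integer in 0..11")
  }
  (as.integer(root_pc) + MAJOR_STEPS) %% 12L
}

#' A fretboard scale shape as an ordered list of scale degrees
#'
#' A shape is described abstractly by the scale degrees it traverses,
#' relative to the key root (degree 0).  Degrees may be negative (below the
#' root) or exceed 6 (upper octaves); they must be strictly increasing and
#' at least 8 long.
#'
#' @param name Shape label (conventionally one of the CAGED letters).
#' @param degrees Strictly increasing integer vector, length >= 8.
#' @return An object of class `scale_shape`.
#' @export
scale_shape <- function(name, degrees) {
  degrees <- as.integer(degrees)
  if (length(degrees) < 8L) stop("a scale shape needs at least 8 degrees")
  if (any(diff(degrees) <= 0L)) stop("shape degrees must be strictly increasing")
  structure(list(name = name, degrees = degrees), class = "scale_shape")
}

#' Default two-octave scale shapes in CAGED order
#'
#' Four box patterns (E, D, C, A) spanning roughly two octaves each.  The E
#' shape starts on the leading tone below the root, so in G# major its first
#' three tones are G, G#, A#; successive shapes start on successively higher
#' degrees, mimicking the climb up the fretboard.
#'
#' @return Named list of [scale_shape()] objects.
#' @export
default_shapes <- function() {
  list(
    E = scale_shape("E", -1:13),
    D = scale_shape("D", 1:15),
    C = scale_shape("C", 3:17),
    A = scale_shape("A", 5:19)
  )
}

#' Realize a scale shape as concrete pitches in a key
#'
#' Each degree `d` maps to the key-rooted major-scale tone
#' `anchor + 12 * floor(d / 7) + MAJOR_STEPS[d mod 7]`, where `register_anchor`
#' is the MIDI pitch of the key root (degree 0).
#'
#' @param key_root_pc Pitch class of the key root (0--11).
#' @param shape A [scale_shape()].
#' @param register_anchor MIDI pitch at which the root (degree 0) is placed;
#'   its pitch class must equal `key_root_pc`.
#' @return Data frame with columns `midi`, `pc`, `name`.
#' @export
#' @examples
#' # E shape in G# major opens on the leading tone: G, G#, A#
#' shape_pitches(8, default_shapes()$E, 44)$name[1:3]
shape_pitches <- function(key_root_pc, shape, register_anchor) {
  stopifnot(inherits(shape, "scale_shape"))
  register_anchor <- as.integer(register_anchor)
  if (register_anchor %% 12L != as.integer(key_root_pc)) {
    stop("`register_anchor` pitch class must match `key_root_pc`")
  }
  d <- shape$degrees
  midi <- register_anchor + 12L * (d %/% 7L) + MAJOR_STEPS[d %% 7L + 1L]
  if (any(midi < GUITAR_RANGE[1] | midi > GUITAR_RANGE[2])) {
    stop("shape realization leaves the guitar range [E2, E6]")
  }
  data.frame(midi = midi, pc = midi %% 12L, name = pitch_name(midi),
             stringsAsFactors = FALSE)
}

#' Expand pitches into overlapping sliding windows
#'
#' Consecutive `window`-note groups advancing by one scale step:
#' `p[1..w], p[2..w+1], ...` concatenated.  Ten pitches with a 3-note window
#' give 24 notes.
#'
#' @param pitches Data frame of notes (as from [shape_pitches()]) or a vector.
#' @param window Window length, default 3.
#' @return Object of the same type as `pitches`, rows repeated in sliding
#'   window order; length `window * (n - window + 1)`.
#' @export
sliding_window_pattern <- function(pitches, window = 3L) {
  n <- if (is.data.frame(pitches)) nrow(pitches) else length(pitches)
  window <- as.integer(window)
  if (window < 1L || window > n) stop("`window` must be in 1..length(pitches)")
  idx <- unlist(lapply(seq_len(n - window + 1L), function(i) i:(i + window - 1L)))
  if (is.data.frame(pitches)) pitches[idx, , drop = FALSE] else pitches[idx]
}
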