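#' 24-channel mobile EEG montage with frontocentral topography
#'
#' The 10--20 positions of a 24-electrode mobile cap (with CPz, Pz, AFz and
#' POz added and two mastoids M1/M2), each with a topographic gain in
#' \[0, 1\] that scales the evoked response.  The default gain map peaks at
#' Fz (frontocentral auditory-evoked topography) and is ~0 at the mastoids,
#' so mastoid re-referencing is approximately signal-neutral.
#'
#' @param fz_gain Gain at Fz (default 1, the maximum).
#' @return Data frame with columns `label` and `gain`, class
#'   `channel_layout`.
#' @export
channel_layout <- function(fz_gain = 1.0) {
  gains <- c(
    Fp1 = 0.55, Fp2 = 0.55, AFz = 0.85,
    F7 = 0.50, F3 = 0.80, Fz = 1.00, F4 = 0.80, F8 = 0.50,
    T7 = 0.35, C3 = 0.70, Cz = 0.90, C4 = 0.70, T8 = 0.35,
    CPz = 0.75,
    P7 = 0.25, P3 = 0.45, Pz = 0.55, P4 = 0.45, P8 = 0.25,
    POz = 0.35, O1 = 0.20, O2 = 0.20,
    M1 = 0.0, M2 = 0.0
  )
  gains["Fz"] <- fz_gain
  out <- data.frame(label = names(gains), gain = unname(gains),
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_layout", "data.frame")
  out
}

#' Mastoid channel labels of a layout
#' @param layout A [channel_layout()].
#' @keywords internal
mastoid_labels <- function(layout) {
  intersect(c("M1", "M2"), layout$label)
}
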