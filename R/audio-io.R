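# Minimal RIFF/WAVE writer and reader (PCM 16-bit and IEEE float32, mono or
# multichannel).  Only the canonical fmt/data chunk layout is supported.

#' Write a waveform as a WAV file
#'
#' @param samples Numeric vector (mono) or channels-in-columns matrix of
#'   amplitudes in \[-1, 1\].
#' @param path Output path.
#' @param fs Sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, path, fs = 44100, bits = 16) {
  if (!bits %in% c(16, 32)) stop("`bits` must be 16 or 32")
  x <- as.matrix(samples)
  n_ch <- ncol(x)
  n <- nrow(x)
  inter <- as.vector(t(x)) # interleave channels
  bytes_per <- bits / 8
  data_len <- n * n_ch * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, inter)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path Input path.
#' @return List with `samples` (matrix, channels in columns) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        n_ch = readBin(con, integer(), size = 2, endian = "little"),
        fs = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little")
      )
      if (len > 16) readBin(con, raw(), n = len - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      n_val <- len / (fmt$bits / 8)
      inter <- if (fmt$bits == 16) {
        readBin(con, integer(), n = n_val, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else {
        readBin(con, numeric(), n = n_val, size = 4, endian = "little")
      }
      samples <- matrix(inter, ncol = fmt$n_ch, byrow = TRUE)
      return(list(samples = samples, fs = fmt$fs))
    } else {
      readBin(con, raw(), n = len)
    }
  }
}
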