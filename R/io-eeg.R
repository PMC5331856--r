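# EEG container: a directory holding a JSON header, raw little-endian
# float32 channel-major samples, a tab-delimited event table, and a 0/1
# byte packet-loss mask.

#' Write an EEG recording to a container directory
#'
#' @param rec An `eeg_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eeg_dir <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    format = "noteERP-eeg-v1",
    fs = rec$fs,
    units = "uV",
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    labels = rec$layout$label,
    gains = rec$layout$gain,
    block_id = rec$block_id,
    subject_id = rec$subject_id,
    data_file = "data.bin",
    events_file = "events.tsv",
    mask_file = "mask.bin"
  )
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.vector(t(rec$data)), con, size = 4, endian = "little")
  close(con)
  utils::write.table(rec$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "mask.bin"), "wb")
  writeBin(as.integer(rec$lost), con, size = 1)
  close(con)
  invisible(dir)
}

#' Read an EEG recording from a container directory
#'
#' @param dir Directory written by [write_eeg_dir()].
#' @return An `eeg_recording` (data at float32 precision).
#' @export
read_eeg_dir <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  if (!identical(header$format, "noteERP-eeg-v1")) {
    stop("not a noteERP EEG container: ", dir)
  }
  n <- header$n_samples
  n_ch <- header$n_channels
  con <- file(file.path(dir, header$data_file), "rb")
  raw_data <- readBin(con, numeric(), n = n * n_ch, size = 4,
                      endian = "little")
  close(con)
  con <- file(file.path(dir, header$mask_file), "rb")
  lost <- as.logical(readBin(con, integer(), n = n, size = 1, signed = FALSE))
  close(con)
  layout <- data.frame(label = header$labels, gain = header$gains,
                       stringsAsFactors = FALSE)
  class(layout) <- c("channel_layout", "data.frame")
  structure(list(
    data = matrix(raw_data, nrow = n_ch, byrow = TRUE),
    fs = header$fs, layout = layout,
    events = utils::read.delim(file.path(dir, header$events_file),
                               stringsAsFactors = FALSE),
    lost = lost, block_id = header$block_id, subject_id = header$subject_id
  ), class = "eeg_recording")
}
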