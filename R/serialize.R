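#' Write / read a recording as a portable text container
#'
#' A recording is stored as a directory of plain-text files: `data.tsv`
#' (samples x channels), `events.tsv`, `attended.tsv`, and `meta.json`
#' (sampling rate, channel labels, segment layout). This keeps synthetic
#' datasets diffable and platform-independent.
#'
#' @param recording A `bci_recording`.
#' @param dir Directory to create/read.
#' @return `dir`, invisibly (writer); a `bci_recording` (reader).
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dat <- tibble::as_tibble(t(recording$data), .name_repair = "minimal")
  names(dat) <- recording$channel_labels
  readr::write_tsv(dat, file.path(dir, "data.tsv"))
  readr::write_tsv(recording$events, file.path(dir, "events.tsv"))
  readr::write_tsv(recording$attended, file.path(dir, "attended.tsv"))
  jsonlite::write_json(
    list(fs_hz = recording$fs_hz, channel_labels = recording$channel_labels,
         pre_s = recording$pre_s, segment_samples = recording$segment_samples),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dat <- readr::read_tsv(file.path(dir, "data.tsv"), show_col_types = FALSE)
  events <- readr::read_tsv(file.path(dir, "events.tsv"), show_col_types = FALSE)
  attended <- readr::read_tsv(file.path(dir, "attended.tsv"), show_col_types = FALSE)
  data <- t(as.matrix(dat))
  rownames(data) <- meta$channel_labels
  structure(
    list(data = data, fs_hz = meta$fs_hz, channel_labels = meta$channel_labels,
         events = events, attended = attended, pre_s = meta$pre_s,
         segment_samples = meta$segment_samples),
    class = "bci_recording"
  )
}
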