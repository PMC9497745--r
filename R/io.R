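#' Write or read a recording as a delimited matrix with a JSON sidecar
#'
#' The signal is stored as a samples x channels TSV (header = channel
#' labels); sampling rate and subject identity go to `<prefix>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `write_recording` returns the prefix invisibly; `read_recording`
#'   returns the `eeg_recording`.
#' @export
write_recording <- function(rec, prefix) {
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  write.table(m, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id,
                            channel_labels = rec$channel_labels),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(paste0(prefix, ".tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE))
  d <- t(m)
  dimnames(d) <- NULL
  eeg_recording(d, meta$fs, meta$channel_labels, meta$subject_id)
}

#' Write banded signals as per-channel, per-band delimited tables
#'
#' One TSV per channel with five band columns (delta..gamma), plus a JSON
#' sidecar with rate and correction flag.
#'
#' @param banded A `banded_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_banded <- function(banded, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(banded$bands)) {
    m <- t(banded$bands[[ch]])
    colnames(m) <- band_names()
    write.table(m, file.path(dir, paste0(banded$channel_labels[ch], ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(fs = banded$fs, subject_id = banded$subject_id,
                            artifact_corrected = banded$artifact_corrected,
                            channel_labels = banded$channel_labels),
                       file.path(dir, "banded.json"), auto_unbox = TRUE)
  invisible(dir)
}
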