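#' Feature-matrix container
#'
#' Rows are (channel, band, feature, scale) streams; columns are
#' non-overlapping 1 s windows aligned to clip starts. Built by
#' [extract_features()].
#'
#' @param values Numeric matrix, feature rows x window columns.
#' @param row_meta Data frame with columns `channel`, `band`, `feature`,
#'   `scale` (NA for single-scale features), one row per matrix row.
#' @param window_times Window start times in seconds on the concatenated
#'   clip-only timeline.
#' @param window_clip Integer clip index per window (optional).
#' @param subject_id Subject identifier.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, row_meta, window_times,
                           window_clip = NULL, subject_id = "subject") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(row_meta),
            ncol(values) == length(window_times))
  structure(list(values = values, row_meta = row_meta,
                 window_times = window_times, window_clip = window_clip,
                 subject_id = subject_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d features x %d windows (%s)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              paste(unique(x$row_meta$feature), collapse = "+")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Extract windowed entropy features from a banded recording
#'
#' Computes the requested entropy features for every channel x band stream
#' over non-overlapping 1 s windows (256 samples at 256 Hz). Windows are
#' aligned to clip starts and never straddle clip boundaries; a trailing
#' partial window within a clip is dropped. With the 12-channel montage the
#' five-scale multiscale feature yields 300 rows and each single entropy 60.
#'
#' Zero-variance windows produce `NaN` in every affected row; they are
#' flagged here and imputed (per feature row) during normalisation.
#'
#' @param banded An artifact-corrected `banded_recording` at 256 Hz.
#' @param params An [entropy_params()].
#' @param features Character subset of `c("mse", "ae", "fe", "re", "de")`.
#' @return A [feature_matrix()] whose rows are ordered channel-major, then
#'   band, then feature (multiscale scales 1..tau_max expand in place).
#' @export
extract_features <- function(banded, params = entropy_params(),
                             features = c("mse", "ae", "fe", "re", "de")) {
  features <- match.arg(features, several.ok = TRUE)
  if (length(banded$bands) == 0 || ncol(banded$bands[[1]]) == 0)
    stop("empty recording: nothing to extract")
  w <- as.integer(banded$fs) # 1 s windows
  n <- ncol(banded$bands[[1]])

  # clip-aligned window starts (0-based for the C++ kernel)
  ci <- banded$clip_index
  if (is.null(ci)) ci <- rep.int(1L, n)
  starts <- integer(0)
  wclip <- integer(0)
  for (k in unique(ci)) {
    idx0 <- which(ci == k)[1] - 1L
    len <- sum(ci == k)
    nw <- len %/% w
    if (nw > 0) {
      starts <- c(starts, idx0 + (seq_len(nw) - 1L) * w)
      wclip <- c(wclip, rep.int(as.integer(k), nw))
    }
  }
  if (length(starts) == 0) stop("empty recording: no complete 1 s window")

  do_mse <- "mse" %in% features
  do_ae <- "ae" %in% features
  do_fe <- "fe" %in% features
  do_re <- "re" %in% features
  do_de <- "de" %in% features
  per_stream <- (if (do_mse) params$tau_max else 0L) +
    do_ae + do_fe + do_re + do_de

  nch <- length(banded$bands)
  bnames <- band_names()
  vals <- matrix(NA_real_, nch * 5 * per_stream, length(starts))
  meta <- vector("list", nch * 5)
  row0 <- 0L
  stream_feat <- c(if (do_mse) rep("mse", params$tau_max),
                   if (do_ae) "ae", if (do_fe) "fe",
                   if (do_re) "re", if (do_de) "de")
  stream_scale <- c(if (do_mse) seq_len(params$tau_max),
                    rep(NA_integer_, do_ae + do_fe + do_re + do_de))
  for (ch in seq_len(nch)) {
    for (b in seq_len(5)) {
      m <- cpp_stream_features(banded$bands[[ch]][b, ], starts, w,
                               params$m, params$r_factor, params$n,
                               params$q, params$histogram_bins,
                               params$tau_max,
                               do_mse, do_ae, do_fe, do_re, do_de)
      vals[row0 + seq_len(per_stream), ] <- m
      meta[[(ch - 1) * 5 + b]] <- data.frame(
        channel = banded$channel_labels[ch], band = bnames[b],
        feature = stream_feat, scale = stream_scale)
      row0 <- row0 + per_stream
    }
  }
  feature_matrix(vals, do.call(rbind, meta),
                 window_times = starts / banded$fs,
                 window_clip = wclip, subject_id = banded$subject_id)
}

#' Serialise a feature matrix to TSV
#'
#' Header comment lines record the subject; row-metadata columns precede the
#' window values.
#'
#' @param fm A [feature_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly; `read_feature_matrix` returns the
#'   `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject=%s", fm$subject_id), con)
  writeLines(paste0("# window_times=", paste(fm$window_times, collapse = ",")), con)
  if (!is.null(fm$window_clip))
    writeLines(paste0("# window_clip=", paste(fm$window_clip, collapse = ",")), con)
  df <- cbind(fm$row_meta, as.data.frame(fm$values))
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- readLines(path, n = 3)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^# ", key, "="), "", ln)
  }
  subject <- field("subject")
  wt <- as.numeric(strsplit(field("window_times"), ",")[[1]])
  wc <- field("window_clip")
  if (!is.null(wc)) wc <- as.integer(strsplit(wc, ",")[[1]])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  meta <- df[, c("channel", "band", "feature", "scale")]
  vals <- as.matrix(df[, -(1:4)])
  dimnames(vals) <- NULL
  feature_matrix(vals, meta, wt, wc, subject)
}
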