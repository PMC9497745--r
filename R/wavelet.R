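#' Multilevel db6 wavelet decomposition and reconstruction
#'
#' `wavedec_db6` decomposes a signal into `J` detail levels plus a final
#' approximation using the Daubechies-6 filter bank with half-sample
#' symmetric boundary extension. `waverec_db6` inverts it exactly (to
#' numerical precision) when the coefficients are unmodified.
#'
#' @param x Numeric signal.
#' @param J Decomposition depth (default 5).
#' @param coeffs A list as returned by `wavedec_db6`.
#' @return `wavedec_db6`: list with `approx` (level-J approximation
#'   coefficients), `details` (list, finest level first), `lens` (internal
#'   bookkeeping); `waverec_db6`: the reconstructed numeric signal.
#' @export
wavedec_db6 <- function(x, J = 5) {
  if (length(x) < 2) stop("signal too short for wavelet decomposition")
  cpp_wavedec(as.numeric(x), as.integer(J))
}

#' @rdname wavedec_db6
#' @export
waverec_db6 <- function(coeffs) {
  cpp_waverec(coeffs$approx, coeffs$details, coeffs$lens)
}

#' Threshold one wavelet coefficient level
#'
#' Computes the artifact threshold `T = mean(c) + 2 * sd(c)` (sample standard
#' deviation) and halves, in a single pass, every coefficient whose magnitude
#' exceeds it. Artifact coefficients are typically much larger than those of
#' ongoing EEG, so this attenuates transients while leaving the bulk of the
#' signal untouched.
#'
#' @param c_j Numeric coefficient sequence (length at least 2).
#' @return List with `threshold` (the value of `T`) and `coefficients` (the
#'   corrected sequence).
#' @export
#' @examples
#' threshold_level(c(rep(0, 9), 10))
threshold_level <- function(c_j) {
  if (length(c_j) < 2)
    stop("insufficient data: need at least 2 coefficients")
  T_j <- mean(c_j) + 2 * sd(c_j)
  out <- ifelse(abs(c_j) > T_j, c_j / 2, c_j)
  list(threshold = T_j, coefficients = out)
}

# bands of a 5-level db6 decomposition at 256 Hz; D1 (64-128 Hz) is dropped
band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Decompose a 256 Hz recording into the five clinical bands
#'
#' Five-level db6 decomposition per channel; each band is the reconstruction
#' from a single coefficient set: D2 gives gamma (~32-64 Hz), D3 beta
#' (~16-32), D4 alpha (~8-16), D5 theta (~4-8) and the approximation A5 delta
#' (~0-4 Hz). The finest details D1 (64-128 Hz) fall outside the named bands
#' and are discarded. Every band signal has the length of the input.
#'
#' @param rec An [eeg_recording()] sampled at 256 Hz.
#' @return An object of class `banded_recording`: list with `bands` (list of
#'   channels, each a 5 x n matrix with rows delta..gamma), `fs`,
#'   `channel_labels`, `subject_id`, `artifact_corrected` flag. Clip-index
#'   attributes of `rec` are carried over.
#' @export
band_decompose <- function(rec) {
  if (rec$fs != 256)
    stop("wrong rate: band decomposition expects a 256 Hz recording")
  nch <- nrow(rec$data)
  bands <- vector("list", nch)
  for (ch in seq_len(nch)) {
    # columns: D1..D5 then A5
    rc <- cpp_band_reconstruct(rec$data[ch, ], 5L)
    m <- rbind(delta = rc[, 6], theta = rc[, 5], alpha = rc[, 4],
               beta = rc[, 3], gamma = rc[, 2])
    bands[[ch]] <- m
  }
  structure(list(bands = bands, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id,
                 artifact_corrected = FALSE,
                 clip_index = attr(rec, "clip_index"),
                 clip_labels = attr(rec, "clip_labels")),
            class = "banded_recording")
}

#' @export
print.banded_recording <- function(x, ...) {
  cat(sprintf("<banded_recording> %s: %d channels x 5 bands x %d samples @ %g Hz%s\n",
              x$subject_id, length(x$bands), ncol(x$bands[[1]]), x$fs,
              if (x$artifact_corrected) " (artifact-corrected)" else ""))
  invisible(x)
}

#' Wavelet-threshold artifact removal per band
#'
#' Each band signal is re-decomposed (db6, 5 levels), every coefficient level
#' (details and approximation) is corrected by [threshold_level()], and the
#' signal reconstructed. A single halving pass is applied per level; the
#' procedure is contractive on large transients but not idempotent.
#'
#' @param banded A `banded_recording` from [band_decompose()].
#' @return The corrected `banded_recording`, flagged `artifact_corrected`.
#' @export
remove_artifacts <- function(banded) {
  for (ch in seq_along(banded$bands)) {
    for (b in seq_len(nrow(banded$bands[[ch]]))) {
      banded$bands[[ch]][b, ] <-
        cpp_artifact_correct(banded$bands[[ch]][b, ], 5L)
    }
  }
  banded$artifact_corrected <- TRUE
  banded
}

#' Full preprocessing pipeline for one subject
#'
#' Channel selection, downsampling to 256 Hz, clip-segment extraction, 50 Hz
#' notch, band decomposition, and wavelet-threshold artifact removal, in that
#' order.
#'
#' @param rec Raw [eeg_recording()].
#' @param protocol The subject's [clip_protocol()].
#' @param channels Channels to keep (default: the twelve lateral-temporal
#'   electrodes if present, otherwise all channels).
#' @param target_fs Analysis rate (default 256 Hz).
#' @return An artifact-corrected `banded_recording` carrying per-sample clip
#'   indices.
#' @export
preprocess_subject <- function(rec, protocol, channels = NULL,
                               target_fs = 256) {
  if (is.null(channels)) {
    channels <- if (all(lateral_temporal_channels() %in% rec$channel_labels))
      lateral_temporal_channels() else rec$channel_labels
  }
  rec <- select_channels(rec, channels)
  rec <- downsample(rec, target_fs)
  rec <- extract_clip_segments(rec, protocol)
  rec <- notch_50hz(rec)
  banded <- band_decompose(rec)
  remove_artifacts(banded)
}
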