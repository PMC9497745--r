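#' Per-subject min-max normalisation to \[-1, 1\]
#'
#' Each feature row of the subject's matrix is mapped linearly so its minimum
#' becomes -1 and its maximum +1, removing inter-subject scale differences
#' before cross-subject classification. Constant rows map to 0. `NaN` entries
#' (flagged zero-variance windows) are first imputed with the row median.
#'
#' @param fm A [feature_matrix()] for one subject.
#' @return The normalised `feature_matrix`.
#' @export
#' @examples
#' # a row (0, 5, 10) maps to (-1, 0, 1)
normalize_features <- function(fm) {
  v <- fm$values
  if (length(v) == 0) stop("empty feature matrix")
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    bad <- !is.finite(row)
    if (any(bad)) {
      med <- median(row[!bad])
      if (!is.finite(med)) med <- 0
      row[bad] <- med
    }
    lo <- min(row); hi <- max(row)
    v[i, ] <- if (hi > lo) 2 * (row - lo) / (hi - lo) - 1 else rep(0, length(row))
  }
  fm$values <- v
  fm
}

#' Per-window emotion labels from the clip protocol
#'
#' Builds the label sequence aligned to a feature matrix: every window takes
#' the label of the clip it lies in.
#'
#' @param protocol A [clip_protocol()].
#' @param windows Either a [feature_matrix()] (whose per-window clip indices
#'   are used and validated against the protocol) or an integer vector giving
#'   the number of windows in each clip.
#' @return An object of class `labeled_sequence`: list with `labels`
#'   (integers in -1/0/1), `clip_index`, and `window_times` when available.
#' @export
build_labels <- function(protocol, windows) {
  lab <- protocol$clips$label
  if (inherits(windows, "feature_matrix")) {
    wc <- windows$window_clip
    if (is.null(wc))
      stop("alignment error: feature matrix carries no clip indices")
    if (max(wc) > length(lab))
      stop("alignment error: feature matrix references clips beyond the protocol")
    labels <- lab[wc]
    out <- list(labels = labels, clip_index = wc,
                window_times = windows$window_times)
  } else {
    windows <- as.integer(windows)
    if (length(windows) != length(lab))
      stop("alignment error: need one window count per clip")
    labels <- rep.int(lab, windows)
    out <- list(labels = labels,
                clip_index = rep.int(seq_along(lab), windows),
                window_times = NULL)
  }
  structure(out, class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1, 0, 1)))
  cat(sprintf("<labeled_sequence> %d windows (neg/neu/pos = %d/%d/%d)\n",
              length(x$labels), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Fuse entropy feature matrices by row concatenation
#'
#' Stacks several feature matrices of the same subject (same windows) into
#' one fused matrix; e.g. the five entropy features fuse to 60 x 4 + 300 =
#' 540 rows for the 12-channel montage.
#'
#' @param features List of [feature_matrix()] objects with identical column
#'   counts and window times.
#' @return A single fused `feature_matrix`.
#' @export
fuse_features <- function(features) {
  if (length(features) == 0) stop("nothing to fuse")
  if (length(features) == 1) return(features[[1]])
  ref <- features[[1]]
  for (f in features[-1]) {
    if (ncol(f$values) != ncol(ref$values) ||
        !isTRUE(all.equal(f$window_times, ref$window_times)))
      stop("alignment error: feature matrices have mismatched windows")
  }
  feature_matrix(do.call(rbind, lapply(features, function(f) f$values)),
                 do.call(rbind, lapply(features, function(f) f$row_meta)),
                 ref$window_times, ref$window_clip, ref$subject_id)
}

#' Random cross-subject train/test split
#'
#' Partitions the subject identifiers into a training and a testing group,
#' deterministically under `seed`. A typical design holds out 5 of 23
#' subjects.
#'
#' @param ids Character vector of subject identifiers.
#' @param n_test Number of test subjects (`< length(ids)`).
#' @param seed Integer seed.
#' @return An object of class `cohort_split`: list with `train_ids`,
#'   `test_ids`, `seed`.
#' @export
split_subjects <- function(ids, n_test = 5, seed = 1) {
  if (n_test >= length(ids))
    stop("invalid split: n_test must be smaller than the number of subjects")
  if (n_test < 1) stop("invalid split: need at least one test subject")
  test <- with_seed(seed, sample(ids, n_test))
  structure(list(train_ids = setdiff(ids, test), test_ids = test,
                 seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d train / %d test (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Write or read a split manifest as JSON
#'
#' @param split A [split_subjects()] result.
#' @param path JSON path.
#' @return `path` invisibly; `read_split` returns the `cohort_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train_ids = split$train_ids,
                            test_ids = split$test_ids,
                            seed = split$seed),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = x$train_ids, test_ids = x$test_ids,
                 seed = as.integer(x$seed)),
            class = "cohort_split")
}
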