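#' Preprocess a cohort and extract all entropy features
#'
#' Runs every subject through the full preprocessing pipeline
#' ([preprocess_subject()]), extracts the five entropy feature families in
#' one pass, normalises per subject, and builds the aligned label sequences.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()], or any list with
#'   `recordings`, `protocol`, `subject_ids`.
#' @param params An [entropy_params()].
#' @param normalize Normalise each subject's features to \[-1, 1\]
#'   (default TRUE).
#' @param verbose Print one line per subject.
#' @return An object of class `cohort_features`: list with `features` (per
#'   subject, the full fused [feature_matrix()]), `labels` (per subject
#'   `labeled_sequence`), `subject_ids`.
#' @export
extract_cohort_features <- function(cohort, params = entropy_params(),
                                    normalize = TRUE, verbose = FALSE) {
  n <- length(cohort$recordings)
  feats <- vector("list", n)
  labs <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose)
      message("processing subject ", cohort$subject_ids[i])
    banded <- preprocess_subject(cohort$recordings[[i]], cohort$protocol)
    fm <- extract_features(banded, params)
    if (normalize) fm <- normalize_features(fm)
    feats[[i]] <- fm
    labs[[i]] <- build_labels(cohort$protocol, fm)
  }
  structure(list(features = feats, labels = labs,
                 subject_ids = cohort$subject_ids),
            class = "cohort_features")
}

#' Restrict a feature matrix to one feature family
#'
#' @param fm A [feature_matrix()].
#' @param feature One of `"mse"`, `"ae"`, `"fe"`, `"re"`, `"de"`, or
#'   `"all"` (identity).
#' @return The row-subset `feature_matrix`.
#' @export
subset_features <- function(fm, feature) {
  feature <- tolower(feature)
  if (feature == "all") return(fm)
  keep <- fm$row_meta$feature == feature
  if (!any(keep))
    stop("configuration error: feature set '", feature,
         "' not present in the matrix")
  feature_matrix(fm$values[keep, , drop = FALSE],
                 fm$row_meta[keep, , drop = FALSE],
                 fm$window_times, fm$window_clip, fm$subject_id)
}

#' Benchmark LSTM and BiLSTM over the six feature sets
#'
#' Trains both architectures on each single-entropy feature set and on the
#' fused set ("ALL"), using a cross-subject split, and reports the mean
#' test-subject accuracy for every cell of the 2 x 6 grid.
#'
#' @param cohort_feats A `cohort_features` object from
#'   [extract_cohort_features()].
#' @param split A `cohort_split` from [split_subjects()]; defaults to a
#'   5-subject hold-out under `seed`.
#' @param feature_sets Character vector of feature sets to benchmark.
#' @param architectures Character vector among `"lstm"`, `"bilstm"`.
#' @param seed Seed for the default split and network initialisation.
#' @param ... Passed to [seq_lstm()] (e.g. `hidden`, `lr`, `max_epochs`).
#' @return An object of class `entropy_benchmark`: list with `accuracy`
#'   (architectures x feature sets matrix), `models` configuration, `split`.
#' @export
run_benchmark <- function(cohort_feats, split = NULL,
                          feature_sets = c("ae", "fe", "re", "de", "mse", "all"),
                          architectures = c("lstm", "bilstm"),
                          seed = 1, ...) {
  if (is.null(split))
    split <- split_subjects(cohort_feats$subject_ids, n_test = 5, seed = seed)
  ids <- cohort_feats$subject_ids
  tr <- match(split$train_ids, ids)
  te <- match(split$test_ids, ids)
  if (anyNA(tr) || anyNA(te)) stop("split references unknown subjects")
  acc <- matrix(NA_real_, length(architectures), length(feature_sets),
                dimnames = list(architectures, toupper(feature_sets)))
  for (fi in seq_along(feature_sets)) {
    fset <- feature_sets[fi]
    xtr <- lapply(cohort_feats$features[tr], subset_features, feature = fset)
    xte <- lapply(cohort_feats$features[te], subset_features, feature = fset)
    for (ai in seq_along(architectures)) {
      model <- seq_lstm(xtr, cohort_feats$labels[tr],
                        architecture = architectures[ai], seed = seed, ...)
      test_data <- lapply(seq_along(te), function(j)
        list(features = xte[[j]], labels = cohort_feats$labels[[te[j]]]))
      acc[ai, fi] <- evaluate_model(model, test_data)$accuracy
    }
  }
  structure(list(accuracy = acc, split = split, seed = seed),
            class = "entropy_benchmark")
}

#' @export
print.entropy_benchmark <- function(x, ...) {
  cat("Mean test-subject accuracy (%):\n")
  print(round(100 * x$accuracy, 2))
  invisible(x)
}
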