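#' Fit a sequence-to-sequence LSTM or BiLSTM emotion classifier
#'
#' Trains a recurrent network that assigns one of the three emotion labels
#' (-1, 0, 1) to every 1 s window of a subject's feature sequence. The
#' architecture is the standard LSTM cell (sigmoid input/forget/output gates,
#' tanh candidate, elementwise cell-state update); the bidirectional variant
#' runs a second cell over the reversed sequence and concatenates the hidden
#' states before a per-window softmax output layer. Training minimises the
#' mean per-window cross-entropy over whole-subject sequences by full-batch
#' backpropagation through time with Adam, single-threaded and exactly
#' reproducible under `seed`.
#'
#' When `validation > 0` that many training sequences are held out to monitor
#' generalisation; the parameters of the best-validation epoch are kept and
#' training stops early after `patience` epochs without improvement.
#'
#' @param x List of [feature_matrix()] objects (or plain feature x window
#'   matrices), one per training subject; all must share the feature
#'   dimension.
#' @param y List of `labeled_sequence` objects (or integer vectors in
#'   -1/0/1), aligned window-for-window with `x`.
#' @param architecture `"bilstm"` (default) or `"lstm"`.
#' @param hidden Hidden units per direction (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs Maximum training epochs (default 100).
#' @param validation Number of training sequences held out for early
#'   stopping (default 1; 0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param min_epochs Burn-in epochs before early stopping may select or stop
#'   (guards against a noisy validation subject freezing a barely trained
#'   model).
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param seed Integer seed for initialisation and the validation hold-out.
#' @return An object of class `seq_lstm` with parameters, the per-epoch
#'   training/validation loss log, and the configuration snapshot.
#' @seealso [predict.seq_lstm()], [evaluate_model()], [run_benchmark()]
#' @export
seq_lstm <- function(x, y, architecture = c("bilstm", "lstm"), hidden = 64,
                     lr = 1e-3, max_epochs = 100, validation = 1,
                     patience = 8, min_epochs = 10, clip_norm = 5, seed = 1) {
  architecture <- match.arg(architecture)
  if (length(x) == 0) stop("empty training set")
  if (length(x) != length(y))
    stop("shape error: need one label sequence per feature sequence")
  xs <- lapply(x, as_feature_values)
  ys <- lapply(y, as_label_codes)
  d <- unique(vapply(xs, nrow, 0L))
  if (length(d) != 1) stop("shape error: sequences differ in feature dimension")
  for (i in seq_along(xs))
    if (ncol(xs[[i]]) != length(ys[[i]]))
      stop("shape error: labels not aligned with feature windows")

  n_seq <- length(xs)
  if (validation >= n_seq) validation <- max(0L, n_seq - 1L)
  val_idx <- if (validation > 0)
    with_seed(seed + 1L, sample(n_seq, validation)) else integer(0)
  tr_idx <- setdiff(seq_len(n_seq), val_idx)

  prm <- init_lstm_params(d, hidden, bidirectional = architecture == "bilstm",
                          seed = seed)
  tr <- make_batches(xs[tr_idx], ys[tr_idx])
  val <- if (length(val_idx) > 0) make_batches(xs[val_idx], ys[val_idx]) else NULL
  fit <- cpp_lstm_train(prm, tr$x, tr$y, lr, as.integer(max_epochs),
                        clip_norm, val, as.integer(patience),
                        as.integer(min_epochs))
  structure(list(params = fit$params, architecture = architecture,
                 hidden = hidden, input_dim = d, classes = c(-1L, 0L, 1L),
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 best_epoch = fit$best_epoch,
                 config = list(lr = lr, max_epochs = max_epochs,
                               validation = validation, patience = patience,
                               min_epochs = min_epochs,
                               clip_norm = clip_norm, seed = seed),
                 call = match.call()),
            class = "seq_lstm")
}

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

as_label_codes <- function(y) {
  lab <- if (inherits(y, "labeled_sequence")) y$labels else as.integer(y)
  if (!all(lab %in% c(-1L, 0L, 1L)))
    stop("labels must be -1, 0 or 1")
  as.integer(lab) + 1L # 0..2, class order -1 < 0 < 1
}

# group equal-length sequences into D x B x T cubes
make_batches <- function(xs, ys) {
  lens <- vapply(xs, ncol, 0L)
  out_x <- list(); out_y <- list()
  for (L in unique(lens)) {
    sel <- which(lens == L)
    d <- nrow(xs[[sel[1]]])
    arr <- array(0, c(d, length(sel), L))
    ym <- matrix(0L, L, length(sel))
    for (j in seq_along(sel)) {
      arr[, j, ] <- xs[[sel[j]]]
      ym[, j] <- ys[[sel[j]]]
    }
    out_x[[length(out_x) + 1L]] <- arr
    out_y[[length(out_y) + 1L]] <- ym
  }
  list(x = out_x, y = out_y)
}

# Glorot-uniform weights, forget-gate bias 1
init_lstm_params <- function(d, h, bidirectional, seed) {
  with_seed(seed, {
    gl <- function(nr, nc) {
      s <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -s, s), nr, nc)
    }
    gate_bias <- function() { b <- rep(0, 4 * h); b[(h + 1):(2 * h)] <- 1; b }
    k <- if (bidirectional) 2 * h else h
    prm <- list(bidirectional = bidirectional,
                Wf = gl(4 * h, d), Uf = gl(4 * h, h), bf = gate_bias(),
                Wo = gl(3, k), bo = rep(0, 3))
    if (bidirectional) {
      prm$Wb <- gl(4 * h, d); prm$Ub <- gl(4 * h, h); prm$bb <- gate_bias()
    }
    prm
  })
}

#' @export
print.seq_lstm <- function(x, ...) {
  cat(sprintf("<seq_lstm> %s: %d features -> %d hidden/direction -> 3 classes\n",
              toupper(x$architecture), x$input_dim, x$hidden))
  cat(sprintf("  trained %d epochs, final loss %.4f%s\n",
              length(x$train_loss), tail(x$train_loss, 1),
              if (length(x$val_loss) > 0)
                sprintf(", best validation epoch %d", x$best_epoch) else ""))
  invisible(x)
}

#' @export
summary.seq_lstm <- function(object, ...) {
  np <- sum(vapply(coef(object), length, 0L))
  cat(sprintf("Sequence classifier (%s)\n", toupper(object$architecture)))
  cat(sprintf("  input features : %d\n", object$input_dim))
  cat(sprintf("  hidden units   : %d per direction\n", object$hidden))
  cat(sprintf("  parameters     : %d\n", np))
  cat(sprintf("  epochs run     : %d (max %d)\n",
              length(object$train_loss), object$config$max_epochs))
  cat(sprintf("  final train CE : %.4f nats/window\n",
              tail(object$train_loss, 1)))
  if (length(object$val_loss) > 0)
    cat(sprintf("  best val CE    : %.4f (epoch %d)\n",
                min(object$val_loss), object$best_epoch))
  invisible(object)
}

#' @export
coef.seq_lstm <- function(object, ...) {
  p <- object$params
  p[setdiff(names(p), "bidirectional")]
}

#' @export
plot.seq_lstm <- function(x, ...) {
  ep <- seq_along(x$train_loss)
  plot(ep, x$train_loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy (nats/window)",
       main = sprintf("%s training", toupper(x$architecture)), ...)
  if (length(x$val_loss) > 0) {
    lines(seq_along(x$val_loss), x$val_loss, lty = 2)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Predict per-window emotion labels
#'
#' @param object A fitted [seq_lstm()].
#' @param newdata A [feature_matrix()] (or feature x window matrix) with the
#'   model's input dimension.
#' @param type `"label"` (default) for the hard per-window labels, or
#'   `"posterior"` for the 3 x windows softmax probabilities.
#' @param ... Unused.
#' @return For `type = "label"`, a `labeled_sequence`; ties in the argmax are
#'   broken towards the lower class code (-1 before 0 before 1). For
#'   `type = "posterior"`, a numeric matrix with rows named `-1`, `0`, `1`.
#' @export
predict.seq_lstm <- function(object, newdata, type = c("label", "posterior"),
                             ...) {
  type <- match.arg(type)
  v <- as_feature_values(newdata)
  if (nrow(v) != object$input_dim)
    stop("shape error: feature dimension does not match the model")
  arr <- array(v, c(nrow(v), 1L, ncol(v)))
  post <- cpp_lstm_posterior(object$params, arr) # 3 x 1 x T
  post <- matrix(post, nrow = 3)
  rownames(post) <- c("-1", "0", "1")
  if (type == "posterior") return(post)
  lab <- object$classes[apply(post, 2, which.max)] # which.max: first maximum
  structure(list(labels = lab,
                 clip_index = if (inherits(newdata, "feature_matrix"))
                   newdata$window_clip else NULL,
                 window_times = if (inherits(newdata, "feature_matrix"))
                   newdata$window_times else NULL),
            class = "labeled_sequence")
}

#' Evaluate a classifier on held-out subjects
#'
#' Computes the per-subject fraction of correctly labelled windows, the
#' unweighted mean across test subjects (the headline cross-subject
#' accuracy), and the pooled 3 x 3 confusion matrix.
#'
#' @param model A fitted [seq_lstm()].
#' @param test_data List of `list(features = , labels = )` pairs, one per
#'   test subject.
#' @return List with `per_subject`, `accuracy`, `confusion`.
#' @export
evaluate_model <- function(model, test_data) {
  if (length(test_data) == 0) stop("need at least one test subject")
  acc <- numeric(length(test_data))
  conf <- matrix(0L, 3, 3, dimnames = list(truth = c(-1, 0, 1),
                                           predicted = c(-1, 0, 1)))
  for (i in seq_along(test_data)) {
    truth <- if (inherits(test_data[[i]]$labels, "labeled_sequence"))
      test_data[[i]]$labels$labels else as.integer(test_data[[i]]$labels)
    pred <- predict(model, test_data[[i]]$features)$labels
    acc[i] <- mean(pred == truth)
    for (k in seq_along(truth))
      conf[truth[k] + 2L, pred[k] + 2L] <- conf[truth[k] + 2L, pred[k] + 2L] + 1L
  }
  names(acc) <- vapply(test_data, function(d) {
    if (inherits(d$features, "feature_matrix")) d$features$subject_id else ""
  }, "")
  list(per_subject = acc, accuracy = mean(acc), confusion = conf)
}
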