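#' Construct a film-clip stimulation protocol
#'
#' A protocol is an ordered list of emotional film clips, each labelled
#' positive (1), neutral (0) or negative (-1), preceded by a picture hint and
#' followed by a self-assessment interval.
#'
#' @param labels Integer vector of clip labels in `{-1, 0, 1}`, in
#'   presentation order.
#' @param clip_s Clip duration in seconds (default 120, i.e. two-minute clips).
#' @param hint_s Picture-hint duration before each clip (default 5 s).
#' @param interval_s Self-assessment interval after each clip (default 45 s).
#' @return An object of class `clip_protocol`.
#' @seealso [generate_protocol()] for a label-balanced randomised protocol.
#' @export
clip_protocol <- function(labels, clip_s = 120, hint_s = 5, interval_s = 45) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 0L, 1L)))
    stop("clip labels must be -1 (negative), 0 (neutral) or 1 (positive)")
  if (length(clip_s) == 1) clip_s <- rep(clip_s, length(labels))
  if (any(clip_s <= 0) || hint_s < 0 || interval_s < 0)
    stop("durations must be positive")
  structure(
    list(clips = data.frame(label = labels, duration_s = clip_s),
         hint_s = hint_s, interval_s = interval_s),
    class = "clip_protocol")
}

#' @export
print.clip_protocol <- function(x, ...) {
  tab <- table(factor(x$clips$label, levels = c(-1, 0, 1)))
  cat(sprintf(
    "<clip_protocol> %d clips (neg/neu/pos = %d/%d/%d), %g s each, hint %g s, interval %g s\n",
    nrow(x$clips), tab[1], tab[2], tab[3],
    x$clips$duration_s[1], x$hint_s, x$interval_s))
  invisible(x)
}

#' Generate a balanced, pseudo-randomly ordered protocol
#'
#' Produces `n_clips` two-minute clips with equal counts of the three emotion
#' labels, in an order shuffled deterministically under `seed`. Typical
#' film-clip studies use either 15 or 21 clips per subject.
#'
#' @param n_clips Number of clips; must be divisible by 3.
#' @param seed Integer seed controlling the clip order.
#' @param clip_s,hint_s,interval_s Segment durations in seconds; see
#'   [clip_protocol()].
#' @return A `clip_protocol`.
#' @export
#' @examples
#' generate_protocol(15, seed = 1)
generate_protocol <- function(n_clips = 15, seed = 1, clip_s = 120,
                              hint_s = 5, interval_s = 45) {
  if (n_clips %% 3 != 0)
    stop("invalid protocol: n_clips must be divisible by 3 ",
         "to balance the three emotion labels")
  labels <- rep(c(-1L, 0L, 1L), n_clips / 3)
  ord <- with_seed(seed, sample.int(n_clips))
  clip_protocol(labels[ord], clip_s = clip_s, hint_s = hint_s,
                interval_s = interval_s)
}

# clip start/end times (seconds) on the hint-clip-interval timeline
protocol_timeline <- function(protocol) {
  d <- protocol$clips$duration_s
  n <- length(d)
  block <- protocol$hint_s + d + protocol$interval_s
  start <- cumsum(c(0, head(block, -1))) + protocol$hint_s
  data.frame(clip = seq_len(n), label = protocol$clips$label,
             start_s = start, end_s = start + d)
}

# total timeline duration in seconds
protocol_duration <- function(protocol) {
  sum(protocol$hint_s + protocol$clips$duration_s + protocol$interval_s)
}

#' Write or read a protocol as a TSV file
#'
#' Columns: `clip_index`, `label`, `start_s`, `end_s`. Hint and interval
#' durations are recoverable from the gaps and are stored as a header comment.
#'
#' @param protocol A [clip_protocol()].
#' @param path Path to a TSV file.
#' @return `read_protocol` returns a `clip_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  tl <- protocol_timeline(protocol)
  tl <- data.frame(clip_index = tl$clip, label = tl$label,
                   start_s = tl$start_s, end_s = tl$end_s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hint_s=%g interval_s=%g",
                     protocol$hint_s, protocol$interval_s), con)
  write.table(tl, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  hdr <- readLines(path, n = 1)
  hint_s <- 5; interval_s <- 45
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=")[[1]]
      if (parts[1] == "hint_s") hint_s <- as.numeric(parts[2])
      if (parts[1] == "interval_s") interval_s <- as.numeric(parts[2])
    }
  }
  tl <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  clip_protocol(tl$label, clip_s = tl$end_s - tl$start_s,
                hint_s = hint_s, interval_s = interval_s)
}
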