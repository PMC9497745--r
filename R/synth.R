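#' Configuration of the synthetic emotion-EEG generator
#'
#' The generator emulates the statistical structure that makes emotional EEG
#' classifiable from lateral-temporal channels, without attempting
#' physiological realism: per-band oscillations whose amplitude depends on the
#' emotion being elicited, a pink (1/f) background whose proportion of the
#' clip variance encodes signal complexity, and occasional blink and movement
#' artifacts.
#'
#' Emotion structure follows the ordering reported for real film-clip EEG:
#' gamma-band power positive > negative > neutral, and broadband complexity
#' positive (0.55) roughly equal to negative (0.50), both above neutral
#' (0.35).
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param n_channels Number of channels (default 12, the lateral-temporal
#'   montage).
#' @param fs Native sampling rate in Hz (default 1000, so the downsampling
#'   stage is exercised); must be at least 512.
#' @param band_power_map Named list (`"-1"`, `"0"`, `"1"`) of length-5 numeric
#'   vectors: multiplicative gain per band (delta, theta, alpha, beta, gamma)
#'   for each emotion.
#' @param complexity_map Named numeric vector (`"-1"`, `"0"`, `"1"`): the
#'   proportion of clip-signal variance carried by broadband noise, in
#'   `[0, 1)`.
#' @param artifact_rate Artifact events per minute (blinks and movement
#'   bursts combined; roughly 4:1 blink:movement).
#' @param seed Integer master seed for the cohort.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 23, n_channels = 12, fs = 1000,
                         band_power_map = default_band_power_map(),
                         complexity_map = c(`-1` = 0.50, `0` = 0.35, `1` = 0.55),
                         artifact_rate = 5, seed = 1) {
  if (fs < 512) stop("native sampling rate must be at least 512 Hz")
  if (n_subjects < 1) stop("need at least one subject")
  stopifnot(all(names(band_power_map) %in% c("-1", "0", "1")),
            length(band_power_map) == 3)
  if (any(unlist(band_power_map) <= 0)) stop("band gains must be positive")
  if (any(complexity_map < 0 | complexity_map >= 1))
    stop("complexity proportions must lie in [0, 1)")
  structure(list(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
                 band_power_map = band_power_map,
                 complexity_map = complexity_map,
                 artifact_rate = artifact_rate, seed = seed),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_band_power_map <- function() {
  # delta, theta, alpha, beta, gamma gains per emotion; moderate effects so
  # cross-subject accuracies land in the range typical of film-clip EEG
  list(`-1` = c(1, 1, 1, 1.15, 1.3),
       `0`  = c(1, 1, 1, 1.00, 1.0),
       `1`  = c(1, 1, 1, 1.30, 1.6))
}

# baseline per-band oscillation amplitudes (uV) and centre frequencies (Hz);
# centres sit inside the dyadic bands of a 256 Hz 5-level decomposition
synth_band_amp <- c(delta = 20, theta = 10, alpha = 15, beta = 8, gamma = 6)
synth_band_freq <- c(delta = 2, theta = 6, alpha = 10, beta = 24, gamma = 45)

#' Generate one synthetic subject
#'
#' Builds a recording spanning the full hint/clip/interval timeline at the
#' native rate. Within each clip every channel is a sum of five band-limited
#' sinusoids (random phase and slight frequency jitter per clip) whose
#' amplitudes are scaled by the emotion's band-power gains, plus pink noise
#' scaled so that it carries the emotion's complexity proportion of the clip
#' variance, plus injected blink transients (raised cosine, 0.3-0.5 s) and
#' broadband movement bursts (1-2 s). Hint and interval periods carry
#' neutral-like background activity. Output is deterministic given
#' `subject_seed`.
#'
#' @param protocol A [clip_protocol()].
#' @param config A [synth_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stored in the recording.
#' @return An [eeg_recording()].
#' @export
generate_subject <- function(protocol, config, subject_seed,
                             subject_id = sprintf("S%03d", subject_seed %% 1000)) {
  with_seed(subject_seed, {
    fs <- config$fs
    n <- round(protocol_duration(protocol) * fs)
    nch <- config$n_channels
    tl <- protocol_timeline(protocol)
    nclip <- nrow(tl)

    # subject- and channel-level gain jitter so cross-subject normalisation
    # is non-trivial
    subj_gain <- exp(rnorm(1, 0, 0.2))
    chan_gain <- exp(rnorm(nch, 0, 0.1))
    # subjects respond to emotions with different strength per band, and
    # individual clips of the same emotion differ in how strongly they elicit
    # it; both keep cross-subject generalisation honest
    emo_jitter <- matrix(exp(rnorm(5 * 3, 0, 0.15)), 5, 3,
                         dimnames = list(NULL, c("-1", "0", "1")))
    clip_jitter <- matrix(exp(rnorm(nrow(tl) * 5, 0, 0.2)), nrow(tl), 5)

    # per clip x band x channel phases and per clip x band frequency jitter
    phases <- array(runif(nclip * 5 * nch, 0, 2 * pi), c(nclip, 5, nch))
    base_phases <- matrix(runif(5 * nch, 0, 2 * pi), 5, nch)
    fjit <- matrix(runif(nclip * 5, 0.97, 1.03), nclip, 5)

    # artifact schedule (shared event times, per-channel scale)
    n_events <- rpois(1, config$artifact_rate * n / fs / 60)
    ev <- NULL
    if (n_events > 0) {
      ev <- data.frame(
        time = runif(n_events, 0, n / fs),
        blink = runif(n_events) < 0.8)
      ev$dur <- ifelse(ev$blink, runif(n_events, 0.3, 0.5),
                       runif(n_events, 1, 2))
      ev$amp <- ifelse(ev$blink, runif(n_events, 60, 120),
                       runif(n_events, 25, 45))
      ev_scale <- matrix(runif(n_events * nch, 0.3, 1), n_events, nch)
    }

    t_all <- (seq_len(n) - 1) / fs
    seg <- segment_table(protocol, tl, n, fs)
    data <- matrix(0, nch, n)

    cmap <- config$complexity_map
    bmap <- config$band_power_map
    base_var <- sum(synth_band_amp^2) / 2

    for (ch in seq_len(nch)) {
      x <- numeric(n)
      noise_sd <- numeric(n)
      for (s in seq_len(nrow(seg))) {
        idx <- seg$i0[s]:seg$i1[s]
        if (seg$kind[s] == "clip") {
          k <- seg$clip[s]
          lab <- as.character(tl$label[k])
          gains <- bmap[[lab]] * emo_jitter[, lab] * clip_jitter[k, ]
          p <- cmap[[lab]]
          amp <- synth_band_amp * gains * sqrt(1 - p)
          for (b in 1:5) {
            x[idx] <- x[idx] + amp[b] *
              sin(2 * pi * synth_band_freq[b] * fjit[k, b] * t_all[idx] +
                    phases[k, b, ch])
          }
          clip_var <- sum(amp^2) / 2 / (1 - p)
          noise_sd[idx] <- sqrt(p * clip_var)
        } else {
          p0 <- 0.3
          amp <- synth_band_amp * sqrt(1 - p0) * 0.8
          for (b in 1:5) {
            x[idx] <- x[idx] + amp[b] *
              sin(2 * pi * synth_band_freq[b] * t_all[idx] + base_phases[b, ch])
          }
          noise_sd[idx] <- sqrt(p0 * base_var * 0.8^2)
        }
      }
      pn <- pink_noise(n)
      x <- x + pn * noise_sd
      if (!is.null(ev) && nrow(ev) > 0) {
        for (e in seq_len(nrow(ev))) {
          i0 <- floor(ev$time[e] * fs) + 1L
          i1 <- min(n, i0 + round(ev$dur[e] * fs) - 1L)
          if (i0 > n) next
          u <- seq(0, 1, length.out = i1 - i0 + 1L)
          env <- 0.5 * (1 - cos(2 * pi * u))
          if (ev$blink[e]) {
            x[i0:i1] <- x[i0:i1] + ev$amp[e] * ev_scale[e, ch] * env
          } else {
            x[i0:i1] <- x[i0:i1] +
              ev$amp[e] * ev_scale[e, ch] * env * rnorm(length(env))
          }
        }
      }
      # broadband sensor noise floor (uV)
      x <- x + rnorm(n, sd = 3)
      data[ch, ] <- x * subj_gain * chan_gain[ch]
    }

    labels <- if (nch == 12) lateral_temporal_channels() else
      sprintf("CH%02d", seq_len(nch))
    eeg_recording(data, fs, labels, subject_id)
  })
}

# hint/clip/interval segment index table over the sample grid
segment_table <- function(protocol, tl, n, fs) {
  rows <- list()
  pos <- 0
  for (k in seq_len(nrow(tl))) {
    segs <- data.frame(
      kind = c("hint", "clip", "interval"),
      dur = c(protocol$hint_s, protocol$clips$duration_s[k],
              protocol$interval_s),
      clip = k)
    for (s in seq_len(3)) {
      if (segs$dur[s] <= 0) next
      i0 <- floor(pos * fs) + 1L
      pos <- pos + segs$dur[s]
      i1 <- min(n, floor(pos * fs))
      rows[[length(rows) + 1L]] <-
        data.frame(kind = segs$kind[s], clip = k, i0 = i0, i1 = i1)
    }
  }
  do.call(rbind, rows)
}

# pink (1/f) noise with unit standard deviation, via the classic 3-pole
# IIR approximation applied to white noise
pink_noise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  w <- rnorm(n + 2000)
  y <- signal::filter(b, a, w)[-(1:2000)] # drop warm-up
  as.numeric(y / sd(y))
}

#' Generate a synthetic cohort
#'
#' Creates `config$n_subjects` independent subjects sharing one balanced
#' protocol. Subject seeds are derived deterministically from the master seed,
#' so the same configuration always produces the same cohort.
#'
#' @param config A [synth_config()].
#' @param protocol Optional [clip_protocol()]; by default a 15-clip balanced
#'   protocol generated under the cohort seed.
#' @return A list of class `synth_cohort`: elements `recording` (list),
#'   `protocol`, `subject_ids`.
#' @export
generate_cohort <- function(config, protocol = NULL) {
  if (is.null(protocol))
    protocol <- generate_protocol(15, seed = config$seed)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1,
                                             config$n_subjects))
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  recs <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects))
    recs[[i]] <- generate_subject(protocol, config, seeds[i], ids[i])
  structure(list(recordings = recs, protocol = protocol, subject_ids = ids,
                 seeds = seeds),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects, %d clips each\n",
              length(x$recordings), nrow(x$protocol$clips)))
  invisible(x)
}
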