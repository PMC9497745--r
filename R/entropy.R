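#' Entropy-estimation parameters
#'
#' Collects the tunable parameters shared by the windowed entropy features.
#' Defaults follow the standard published definitions: embedding dimension
#' `m = 2`, tolerance 0.2 times the window standard deviation, fuzzy
#' gradient exponent `n = 2`, entropic index `q = 2` (collision entropy),
#' five multiscale scales, and a 10-bin histogram for the Renyi probability
#' estimate.
#'
#' @param m Embedding dimension (template length).
#' @param r_factor Tolerance as a multiple of the window standard deviation.
#' @param n Fuzzy-similarity gradient exponent.
#' @param q Renyi entropic index (`q >= 0`, `q != 1`).
#' @param tau_max Largest multiscale coarse-graining factor.
#' @param histogram_bins Number of equal-width histogram bins for Renyi
#'   probabilities.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, n = 2, q = 2,
                           tau_max = 5, histogram_bins = 10) {
  if (m < 1) stop("embedding dimension m must be at least 1")
  if (r_factor <= 0) stop("tolerance factor must be positive")
  if (q < 0 || q == 1) stop("invalid entropic index: need q >= 0 and q != 1")
  if (tau_max < 1) stop("tau_max must be at least 1")
  structure(list(m = as.integer(m), r_factor = r_factor, n = n, q = q,
                 tau_max = as.integer(tau_max),
                 histogram_bins = as.integer(histogram_bins)),
            class = "entropy_params")
}

#' Coarse-grain a series
#'
#' Replaces each non-overlapping block of `tau` consecutive samples by its
#' mean; trailing samples that do not fill a block are dropped.
#'
#' @param x Numeric series.
#' @param tau Scale factor (positive integer, at most `length(x)`).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
#' @examples
#' coarse_grain(1:6, 2) # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be at least 1")
  if (tau > length(x))
    stop("empty output: tau exceeds the series length")
  nb <- length(x) %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' Negative log of the conditional probability that template vectors matching
#' at length `m` (Chebyshev distance strictly below `r`) also match at length
#' `m + 1`; self-matches are excluded. Returns `NaN` when no matches exist at
#' either length.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r Tolerance (same units as `x`); must be positive.
#' @return Sample entropy in nats (`NaN` if undefined).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) stop("insufficient data for sample entropy")
  if (r <= 0) stop("degenerate tolerance: r must be positive")
  cpp_sample_entropy(as.numeric(x), as.integer(m), r)
}

#' Approximate entropy
#'
#' Difference of log-averaged template-match frequencies at embedding
#' dimensions `m` and `m + 1`, with self-matches included (so no match count
#' is ever zero) and Chebyshev distance at most `r`.
#'
#' @inheritParams sample_entropy
#' @return Approximate entropy in nats.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) stop("insufficient data for approximate entropy")
  if (r < 0) stop("tolerance must be non-negative")
  cpp_approximate_entropy(as.numeric(x), as.integer(m), r)
}

#' Fuzzy entropy
#'
#' Sample-entropy-like statistic in which the hard match indicator is
#' replaced by the fuzzy membership `exp(-(d / r)^n)` of the Chebyshev
#' distance `d` between baseline-removed template vectors (each template has
#' its own mean subtracted); self-matches are excluded.
#'
#' @inheritParams sample_entropy
#' @param n Gradient exponent of the similarity boundary.
#' @return Fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2, n = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) stop("insufficient data for fuzzy entropy")
  if (r <= 0) stop("degenerate tolerance: r must be positive")
  cpp_fuzzy_entropy(as.numeric(x), as.integer(m), n, r)
}

#' Renyi entropy
#'
#' `RE = log(sum(p^q)) / (1 - q)` in nats, with the probabilities `p`
#' estimated as relative frequencies over equal-width histogram bins spanning
#' the window's range. Empty bins contribute nothing; a constant window (all
#' mass in one bin) has zero entropy.
#'
#' @param x Numeric series.
#' @param q Entropic index (`q >= 0`, `q != 1`; default 2, the two-order
#'   collision entropy).
#' @param histogram_bins Number of equal-width bins.
#' @return Renyi entropy in nats.
#' @export
renyi_entropy <- function(x, q = 2, histogram_bins = 10) {
  if (q < 0 || q == 1)
    stop("invalid entropic index: need q >= 0 and q != 1 (Shannon limit not implemented)")
  cpp_renyi_entropy(as.numeric(x), q, as.integer(histogram_bins))
}

#' Differential entropy under a Gaussian approximation
#'
#' For an approximately Gaussian window, the differential entropy has the
#' closed form `0.5 * log(2 * pi * e * sigma^2)` nats, with `sigma^2` the
#' sample variance of the window. A zero-variance window returns `-Inf`.
#'
#' @param x Numeric series (length at least 2).
#' @return Differential entropy in nats (`-Inf` for constant windows).
#' @export
#' @examples
#' differential_entropy(rnorm(10000)) # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
differential_entropy <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  s2 <- var(x)
  if (s2 == 0) return(-Inf)
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Multiscale (sample) entropy
#'
#' Sample entropy of coarse-grained versions of the window at scales
#' `1..tau_max`. The tolerance is fixed from the scale-1 window
#' (`r_factor * sd(x)`) and reused across scales, so scale profiles reflect
#' changing temporal structure rather than changing variance normalisation.
#'
#' @param x Numeric window.
#' @param params An [entropy_params()].
#' @return Numeric vector of length `params$tau_max`; entry `tau` is the
#'   sample entropy at that scale (entry 1 equals `sample_entropy(x)`).
#' @export
multiscale_entropy <- function(x, params = entropy_params()) {
  need <- params$tau_max * (params$m + 2)
  if (length(x) < need)
    stop("insufficient data: window shorter than tau_max * (m + 2)")
  r <- params$r_factor * sd(x)
  if (r <= 0) stop("degenerate tolerance: constant window")
  cpp_multiscale_entropy(as.numeric(x), params$m, r, params$tau_max)
}
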