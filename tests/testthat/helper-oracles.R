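# Naive brute-force oracles, kept deliberately independent of the package's
# optimised C++ kernels: direct double loops over template pairs, written
# from the definitions.

naive_sample_entropy <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  B <- 0; A <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

naive_approximate_entropy <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nv <- N - mm + 1
    cnt <- vapply(1:nv, function(i) {
      sum(vapply(1:nv, function(j) {
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

naive_fuzzy_entropy <- function(x, m, n, r) {
  N <- length(x)
  nt <- N - m
  phi <- function(mm) {
    tm <- sapply(1:nt, function(i) {
      v <- x[i:(i + mm - 1)]
      v - mean(v)
    })
    s <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        s <- s + exp(-(max(abs(tm[, i] - tm[, j])) / r)^n)
      }
    }
    2 * s / (nt * (nt - 1))
  }
  log(phi(m) / phi(m + 1))
}

naive_renyi_entropy <- function(x, q, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(0)
  b <- pmin(floor((x - lo) / ((hi - lo) / bins)) + 1, bins)
  p <- tabulate(b, bins) / length(x)
  log(sum(p[p > 0]^q)) / (1 - q)
}

# small, fast synthetic fixtures shared across test files
tiny_protocol <- function(n_clips = 6, clip_s = 10, seed = 1) {
  generate_protocol(n_clips, seed = seed, clip_s = clip_s)
}

tiny_config <- function(n_subjects = 1, seed = 5) {
  synth_config(n_subjects = n_subjects, seed = seed)
}

tiny_banded <- function(n_clips = 3, clip_s = 8, seed = 9) {
  prot <- generate_protocol(n_clips, seed = seed, clip_s = clip_s)
  rec <- generate_subject(prot, tiny_config(seed = seed), subject_seed = seed)
  preprocess_subject(rec, prot)
}
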