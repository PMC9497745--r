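# Matrix-form brute-force oracles for full 256-sample windows: still direct
# O(N^2) evaluation of every template pair straight from the definitions
# (via outer()), independent of the package's C++ kernels, but fast enough
# to sweep 100 windows.

oracle_se_matrix <- function(x, m, r) {
  nt <- length(x) - m
  D <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    xk <- x[(1 + k):(nt + k)]
    D <- pmax(D, abs(outer(xk, xk, "-")))
  }
  B <- (sum(D < r) - nt) / 2
  xm <- x[(1 + m):(nt + m)]
  D1 <- pmax(D, abs(outer(xm, xm, "-")))
  A <- (sum(D1 < r) - nt) / 2
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

oracle_ae_matrix <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nv <- N - mm + 1
    D <- matrix(0, nv, nv)
    for (k in 0:(mm - 1)) {
      xk <- x[(1 + k):(nv + k)]
      D <- pmax(D, abs(outer(xk, xk, "-")))
    }
    cnt <- rowSums(D <= r) # self-matches included (diagonal is 0)
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

oracle_fe_matrix <- function(x, m, n, r) {
  nt <- length(x) - m
  phi <- function(mm) {
    tm <- sapply(1:nt, function(i) {
      v <- x[i:(i + mm - 1)]
      v - mean(v)
    })
    D <- matrix(0, nt, nt)
    for (k in 1:mm) D <- pmax(D, abs(outer(tm[k, ], tm[k, ], "-")))
    S <- exp(-(D / r)^n)
    (sum(S) - nt) / (nt * (nt - 1))
  }
  log(phi(m) / phi(m + 1))
}
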