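test_that("coarse-graining averages non-overlapping blocks", {
  expect_equal(coarse_grain(1:6, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(c(4, 1, 7), 1), c(4, 1, 7))
  expect_equal(coarse_grain(1:5, 2), c(1.5, 3.5)) # remainder dropped
  expect_error(coarse_grain(1:3, 4), "empty output")
})

test_that("optimised entropies equal the naive double-loop oracles", {
  set.seed(101)
  worst <- c(se = 0, ae = 0, fe = 0, re = 0)
  for (k in 1:25) {
    x <- rnorm(120)
    r <- 0.2 * sd(x)
    se_o <- naive_sample_entropy(x, 2, r)
    se_i <- sample_entropy(x, 2, r)
    if (is.nan(se_o)) expect_true(is.na(se_i)) else
      worst["se"] <- max(worst["se"], abs(se_i - se_o))
    worst["ae"] <- max(worst["ae"],
                       abs(approximate_entropy(x, 2, r) -
                             naive_approximate_entropy(x, 2, r)))
    worst["fe"] <- max(worst["fe"],
                       abs(fuzzy_entropy(x, 2, 2, r) -
                             naive_fuzzy_entropy(x, 2, 2, r)))
    worst["re"] <- max(worst["re"],
                       abs(renyi_entropy(x, 2, 10) -
                             naive_renyi_entropy(x, 2, 10)))
  }
  expect_lt(max(worst), 1e-12)
  # a non-default embedding dimension exercises the generic code path
  y <- rnorm(100)
  ry <- 0.25 * sd(y)
  expect_equal(fuzzy_entropy(y, 3, 2, ry), naive_fuzzy_entropy(y, 3, 2, ry),
               tolerance = 1e-12)
  expect_equal(approximate_entropy(y, 3, ry),
               naive_approximate_entropy(y, 3, ry), tolerance = 1e-12)
})

test_that("closed-form and structural entropy values hold", {
  # periodic series: every m-match extends, so sample entropy is zero
  per <- rep(c(1, 2), 30)
  expect_equal(sample_entropy(per, 2, 0.2 * sd(per)), 0)
  # constant series: approximate entropy vanishes
  expect_equal(approximate_entropy(rep(4, 50), 2, 0.1), 0)
  # uniform occupancy of K bins gives collision entropy log K
  expect_equal(renyi_entropy(rep(1:10, 10), 2, 10), log(10))
  expect_equal(renyi_entropy(rep(7, 20), 2, 10), 0)
  expect_error(renyi_entropy(rnorm(10), 1, 10), "invalid.*index")
  # Gaussian closed form
  x <- rnorm(100)
  x <- (x - mean(x)) / sd(x)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-9)
  expect_equal(differential_entropy(2 * x) - differential_entropy(x), log(2),
               tolerance = 1e-9)
  expect_identical(differential_entropy(rep(1, 10)), -Inf)
})

test_that("entropies are invariant/equivariant under affine maps", {
  set.seed(7)
  x <- rnorm(256)
  r <- 0.2 * sd(x)
  y <- 3.5 * x - 2
  ry <- 0.2 * sd(y)
  expect_equal(sample_entropy(y, 2, ry), sample_entropy(x, 2, r),
               tolerance = 1e-10)
  expect_equal(approximate_entropy(y, 2, ry), approximate_entropy(x, 2, r),
               tolerance = 1e-10)
  expect_equal(fuzzy_entropy(y, 2, 2, ry), fuzzy_entropy(x, 2, 2, r),
               tolerance = 1e-10)
  expect_equal(differential_entropy(3.5 * x) - differential_entropy(x),
               log(3.5), tolerance = 1e-10)
})

test_that("multiscale entropy matches scale-1 sample entropy and declines for white noise", {
  set.seed(11)
  x <- rnorm(256)
  p <- entropy_params()
  mse <- multiscale_entropy(x, p)
  expect_length(mse, 5)
  expect_identical(mse[1], sample_entropy(x, 2, 0.2 * sd(x)))
  expect_equal(length(coarse_grain(x, 5)), 51)
  # white noise: mean profile strictly decreasing across scales
  prof <- matrix(0, 200, 5)
  for (i in 1:200) prof[i, ] <- multiscale_entropy(rnorm(256), p)
  mp <- colMeans(prof, na.rm = TRUE)
  expect_true(all(diff(mp) < 0))
  # 1/f-like noise is flatter across scales than white noise
  pink_prof <- matrix(0, 100, 5)
  for (i in 1:100) {
    w <- rnorm(512)
    pink <- cumsum(w) * 0.25 + w # crude red+white mixture
    pink_prof[i, ] <- multiscale_entropy(pink[129:384], p)
  }
  drop_white <- mp[1] - mp[5]
  pp <- colMeans(pink_prof, na.rm = TRUE)
  expect_lt(pp[1] - pp[5], drop_white)
  expect_error(multiscale_entropy(rnorm(10), p), "insufficient")
})

test_that("entropy outputs are non-negative where defined", {
  set.seed(13)
  for (k in 1:20) {
    x <- rnorm(256)
    r <- 0.2 * sd(x)
    se <- sample_entropy(x, 2, r)
    if (!is.na(se)) expect_gte(se, 0)
    expect_gte(approximate_entropy(x, 2, r), -1e-12)
    expect_gte(fuzzy_entropy(x, 2, 2, r), 0)
    expect_gte(renyi_entropy(x, 2, 10), 0)
  }
})
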