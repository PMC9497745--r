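# small linearly separable sequence task shared by the classifier tests
toy_sequence <- function(T = 60, d = 9, sep = 1.2) {
  lab <- sample(c(-1L, 0L, 1L), T, replace = TRUE)
  x <- matrix(rnorm(d * T, sd = 0.4), d, T)
  for (t in seq_len(T)) {
    hot <- (lab[t] + 1) * 3 + 1:3
    x[hot, t] <- x[hot, t] + sep
  }
  list(x = x, y = lab)
}

test_that("training reduces loss on a separable toy task and is reproducible", {
  set.seed(21)
  dat <- lapply(1:5, function(i) toy_sequence())
  xs <- lapply(dat, `[[`, "x")
  ys <- lapply(dat, `[[`, "y")
  m <- seq_lstm(xs, ys, "bilstm", hidden = 12, lr = 0.02, max_epochs = 40,
                validation = 1, seed = 4)
  expect_lt(tail(m$train_loss, 1), m$train_loss[1] * 0.5)
  # near-monotone decrease within early-stopping patience
  expect_lt(sum(diff(m$train_loss) > 0.02), 3)
  m2 <- seq_lstm(xs, ys, "bilstm", hidden = 12, lr = 0.02, max_epochs = 40,
                 validation = 1, seed = 4)
  expect_identical(m$params$Wf, m2$params$Wf)
  expect_identical(m$train_loss, m2$train_loss)
  # both architectures produce valid fitted models with logged losses
  m3 <- seq_lstm(xs, ys, "lstm", hidden = 12, lr = 0.02, max_epochs = 10,
                 validation = 0, seed = 4)
  expect_s3_class(m3, "seq_lstm")
  expect_length(m3$train_loss, 10)
  expect_error(seq_lstm(list(), list()), "empty")
  expect_error(seq_lstm(xs, lapply(ys, rev)[c(2:5, 1)][1:4], seed = 1),
               "shape|align|length")
})

test_that("prediction yields one normalised posterior per window", {
  set.seed(22)
  dat <- lapply(1:4, function(i) toy_sequence())
  m <- seq_lstm(lapply(dat, `[[`, "x"), lapply(dat, `[[`, "y"),
                "lstm", hidden = 10, lr = 0.02, max_epochs = 25,
                validation = 0, seed = 2)
  te <- toy_sequence(T = 45)
  pred <- predict(m, te$x)
  expect_length(pred$labels, 45)
  expect_true(all(pred$labels %in% c(-1, 0, 1)))
  post <- predict(m, te$x, type = "posterior")
  expect_equal(dim(post), c(3, 45))
  expect_equal(colSums(post), rep(1, 45), tolerance = 1e-6)
  expect_gt(mean(pred$labels == te$y), 0.8)
  expect_error(predict(m, te$x[1:5, ]), "shape")
})

test_that("bilstm has about twice the parameters of lstm", {
  set.seed(23)
  dat <- lapply(1:2, function(i) toy_sequence(T = 20))
  xs <- lapply(dat, `[[`, "x"); ys <- lapply(dat, `[[`, "y")
  a <- seq_lstm(xs, ys, "bilstm", hidden = 8, max_epochs = 1, validation = 0)
  b <- seq_lstm(xs, ys, "lstm", hidden = 8, max_epochs = 1, validation = 0)
  np <- function(m) sum(vapply(coef(m), length, 0L))
  expect_equal(np(a) / np(b), 2, tolerance = 0.05)
})

test_that("evaluation reports per-subject accuracy, their mean and confusion", {
  set.seed(24)
  dat <- lapply(1:4, function(i) toy_sequence())
  m <- seq_lstm(lapply(dat, `[[`, "x"), lapply(dat, `[[`, "y"),
                "bilstm", hidden = 10, lr = 0.02, max_epochs = 25,
                validation = 0, seed = 3)
  te <- lapply(1:2, function(i) {
    s <- toy_sequence()
    list(features = s$x, labels = s$y)
  })
  ev <- evaluate_model(m, te)
  expect_length(ev$per_subject, 2)
  expect_equal(ev$accuracy, mean(ev$per_subject))
  expect_equal(sum(ev$confusion), 120)
  # perfect predictions give accuracy 1 (model predicting its own labels)
  self <- list(list(features = dat[[1]]$x,
                    labels = predict(m, dat[[1]]$x)$labels))
  expect_equal(evaluate_model(m, self)$accuracy, 1)
  # hand-checked unweighted mean
  fake <- list(per_subject = c(0.6, 0.8))
  expect_equal(mean(fake$per_subject), 0.7)
})

test_that("random predictions on balanced labels sit near chance", {
  set.seed(25)
  # an untrained (0-epoch equivalent: 1 epoch, tiny lr) model is near-chance
  dat <- lapply(1:3, function(i) toy_sequence(T = 700, sep = 0))
  m <- seq_lstm(lapply(dat, `[[`, "x"), lapply(dat, `[[`, "y"),
                "lstm", hidden = 6, lr = 1e-5, max_epochs = 1,
                validation = 0, seed = 5)
  te <- toy_sequence(T = 1800, sep = 0)
  acc <- mean(predict(m, te$x)$labels == te$y)
  expect_equal(acc, 1 / 3, tolerance = 0.06)
})
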