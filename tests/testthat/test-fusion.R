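mk_fm <- function(values, subject = "S1", clip = NULL) {
  feature_matrix(values,
                 data.frame(channel = "T7", band = "gamma",
                            feature = rep("de", nrow(values)),
                            scale = NA_integer_),
                 window_times = seq_len(ncol(values)) - 1,
                 window_clip = clip, subject_id = subject)
}

test_that("min-max normalisation maps rows onto [-1, 1]", {
  fm <- mk_fm(rbind(c(0, 5, 10), c(3, 3, 3)))
  out <- normalize_features(fm)
  expect_equal(out$values[1, ], c(-1, 0, 1))
  expect_equal(out$values[2, ], c(0, 0, 0)) # constant row maps to midpoint
  set.seed(1)
  rnd <- normalize_features(mk_fm(matrix(rnorm(50), 5)))
  expect_true(all(rnd$values >= -1 & rnd$values <= 1))
  # idempotent on non-constant rows
  expect_equal(normalize_features(rnd)$values, rnd$values)
})

test_that("label sequences follow the clip protocol", {
  prot <- generate_protocol(15, seed = 1, clip_s = 120)
  lab <- build_labels(prot, rep(120L, 15))
  expect_length(lab$labels, 1800)
  expect_equal(as.vector(table(lab$labels)), rep(600L, 3))
  # labels constant within each clip
  expect_true(all(tapply(lab$labels, lab$clip_index,
                         function(v) length(unique(v)) == 1)))
  single <- clip_protocol(1, clip_s = 10)
  expect_true(all(build_labels(single, 10L)$labels == 1))
  expect_error(build_labels(prot, rep(120L, 14)), "alignment")
})

test_that("fusion stacks rows and preserves windows", {
  a <- mk_fm(matrix(1, 300, 10))
  b <- mk_fm(matrix(2, 60, 10))
  fused <- fuse_features(list(a, b))
  expect_equal(dim(fused), c(360, 10))
  expect_equal(fused$window_times, a$window_times)
  expect_identical(fuse_features(list(a)), a)
  bad <- mk_fm(matrix(0, 60, 9))
  expect_error(fuse_features(list(a, bad)), "alignment")
})

test_that("subject splits are disjoint, exhaustive and seeded", {
  ids <- sprintf("S%02d", 1:23)
  sp <- split_subjects(ids, n_test = 5, seed = 9)
  expect_length(sp$train_ids, 18)
  expect_length(sp$test_ids, 5)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_identical(split_subjects(ids, 5, seed = 9)$test_ids, sp$test_ids)
  expect_false(identical(split_subjects(ids, 5, seed = 10)$test_ids,
                         sp$test_ids))
  expect_error(split_subjects(ids, 23, seed = 1), "invalid split")
  # manifest round trip
  path <- file.path(tempdir(), "split.json")
  write_split(sp, path)
  back <- read_split(path)
  expect_equal(back$train_ids, sp$train_ids)
  expect_equal(back$test_ids, sp$test_ids)
})
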