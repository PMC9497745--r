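test_that("generated protocols are balanced, timed and seeded", {
  for (n in c(15, 21)) {
    p <- generate_protocol(n, seed = 1)
    expect_equal(nrow(p$clips), n)
    expect_equal(as.vector(table(p$clips$label)), rep(n / 3, 3))
    expect_true(all(p$clips$duration_s == 120))
    expect_equal(p$hint_s, 5)
    expect_equal(p$interval_s, 45)
  }
  expect_error(generate_protocol(16, seed = 1), "invalid protocol")
  expect_identical(generate_protocol(15, seed = 3)$clips,
                   generate_protocol(15, seed = 3)$clips)
  # order actually shuffles with the seed
  expect_false(identical(generate_protocol(15, seed = 3)$clips$label,
                         generate_protocol(15, seed = 4)$clips$label))
})

test_that("subject generation is deterministic and spans the timeline", {
  prot <- tiny_protocol()
  cfg <- tiny_config()
  r1 <- generate_subject(prot, cfg, 77)
  r2 <- generate_subject(prot, cfg, 77)
  expect_identical(r1$data, r2$data)
  expect_equal(ncol(r1$data),
               round(sum(prot$hint_s + prot$clips$duration_s +
                           prot$interval_s) * cfg$fs))
  expect_equal(nrow(r1$data), 12)
  expect_false(identical(r1$data, generate_subject(prot, cfg, 78)$data))
})

test_that("gamma-band power is higher in positive than neutral clips", {
  prot <- generate_protocol(15, seed = 2, clip_s = 4)
  cfg <- tiny_config()
  diffs <- vapply(1:10, function(s) {
    rec <- generate_subject(prot, cfg, 1000 + s)
    banded <- preprocess_subject(rec, prot)
    lab <- banded$clip_labels[banded$clip_index]
    g <- banded$bands[[1]]["gamma", ]
    for (ch in 2:length(banded$bands))
      g <- g + banded$bands[[ch]]["gamma", ]
    rms <- function(v) sqrt(mean(v^2))
    rms(g[lab == 1]) - rms(g[lab == 0])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.5)
  expect_gt(mean(diffs), 0)
})

test_that("zero artifact rate stays within the oscillation + noise envelope", {
  prot <- tiny_protocol(3, clip_s = 5)
  cfg <- synth_config(n_subjects = 1, artifact_rate = 0, seed = 2)
  rec <- generate_subject(prot, cfg, 5)
  # max band amplitude sum times gain jitter bounds the oscillatory part;
  # pink noise is light-tailed, so 10 sd of headroom is ample
  env <- sum(c(20, 10, 15, 8, 6) * 2) * exp(3 * 0.2 + 3 * 0.1) + 10 * 25
  expect_lt(max(abs(rec$data)), env)
})

test_that("cohorts have one recording per subject and a fixed seed map", {
  cfg <- synth_config(n_subjects = 3, seed = 42)
  prot <- tiny_protocol(3, clip_s = 4)
  coh1 <- generate_cohort(cfg, prot)
  expect_length(coh1$recordings, 3)
  coh2 <- generate_cohort(cfg, prot)
  expect_identical(coh1$seeds, coh2$seeds)
  expect_identical(coh1$recordings[[2]]$data, coh2$recordings[[2]]$data)
  one <- generate_cohort(synth_config(n_subjects = 1, seed = 42), prot)
  expect_length(one$recordings, 1)
})

test_that("recording round-trips through the delimited writer", {
  prot <- tiny_protocol(3, clip_s = 2)
  rec <- generate_subject(prot, tiny_config(), 9)
  pre <- file.path(tempdir(), "rec_roundtrip")
  write_recording(rec, pre)
  back <- read_recording(pre)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  p2 <- file.path(tempdir(), "prot.tsv")
  write_protocol(prot, p2)
  prot2 <- read_protocol(p2)
  expect_equal(prot2$clips$label, prot$clips$label)
  expect_equal(prot2$clips$duration_s, prot$clips$duration_s)
  expect_equal(prot2$hint_s, prot$hint_s)
})
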