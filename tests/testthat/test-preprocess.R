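test_that("channel selection keeps the wanted channels in order", {
  labels62 <- c(lateral_temporal_channels(),
                sprintf("E%02d", 1:50))
  rec <- eeg_recording(matrix(rnorm(62 * 100), 62), 256, labels62)
  sel <- select_channels(rec)
  expect_equal(nrow(sel$data), 12)
  expect_equal(sel$channel_labels, lateral_temporal_channels())
  expect_equal(sel$data, rec$data[1:12, ])
  # identity when all labels are requested in original order
  expect_equal(select_channels(rec, labels62)$data, rec$data)
  expect_error(select_channels(rec, c("T7", "XX9")), "XX9")
})

test_that("downsampling reaches the target rate and preserves tones", {
  t <- seq(0, 10 - 1e-9, by = 1 / 1000)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), 1000, "T7")
  dn <- downsample(rec, 256)
  expect_equal(dn$fs, 256)
  expect_equal(ncol(dn$data), 2560, tolerance = 1)
  # dominant spectral peak stays at 10 Hz (FFT oracle)
  sp <- abs(fft(dn$data[1, ]))[1:1280]
  expect_equal((which.max(sp) - 1) * 256 / ncol(dn$data), 10)
  # pass-through when rates match
  expect_identical(downsample(rec, 1000), rec)
  expect_error(downsample(rec, 2000), "upsampl")
})

test_that("clip extraction keeps exactly the clip samples with a clip map", {
  prot <- generate_protocol(15, seed = 1, clip_s = 120)
  n <- round(sum(prot$hint_s + prot$clips$duration_s + prot$interval_s) * 256)
  rec <- eeg_recording(matrix(0, 1, n), 256, "T7")
  seg <- extract_clip_segments(rec, prot)
  expect_equal(ncol(seg$data), 15 * 120 * 256) # 460,800
  expect_equal(length(attr(seg, "clip_index")), ncol(seg$data))
  expect_equal(as.vector(table(attr(seg, "clip_index"))), rep(120 * 256, 15))
  # zero hint/interval protocol is the identity on samples
  p0 <- clip_protocol(c(1, 0, -1), clip_s = 2, hint_s = 0, interval_s = 0)
  rec2 <- eeg_recording(matrix(rnorm(6 * 256), 1), 256, "T7")
  seg2 <- extract_clip_segments(rec2, p0)
  expect_equal(seg2$data, rec2$data)
  # protocol that overruns the recording
  expect_error(extract_clip_segments(rec2, prot), "protocol mismatch")
})

test_that("notch removes 50 Hz and spares the passband", {
  t <- seq(0, 8 - 1e-9, by = 1 / 256)
  mains <- eeg_recording(matrix(sin(2 * pi * 50 * t), 1), 256, "T7")
  out <- notch_50hz(mains)
  expect_lt(sd(out$data[1, ]) / sd(mains$data[1, ]), 0.10)
  alpha <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), 256, "T7")
  out2 <- notch_50hz(alpha)
  expect_equal(sd(out2$data[1, ]) / sd(alpha$data[1, ]), 1, tolerance = 0.05)
  z <- eeg_recording(matrix(0, 1, 512), 256, "T7")
  expect_equal(notch_50hz(z)$data, z$data)
  expect_error(notch_50hz(eeg_recording(matrix(0, 1, 100), 100, "T7")),
               "Nyquist")
})

test_that("band decomposition concentrates energy in the right band", {
  t <- seq(0, 10 - 1e-9, by = 1 / 256)
  tones <- c(delta = 2, theta = 6, alpha = 12, beta = 24, gamma = 40)
  for (b in names(tones)) {
    rec <- eeg_recording(matrix(sin(2 * pi * tones[[b]] * t), 1), 256, "T7")
    bd <- band_decompose(rec)
    en <- apply(bd$bands[[1]], 1, function(v) sum(v^2))
    expect_gt(en[[b]] / sum(en), 0.6)
    expect_equal(ncol(bd$bands[[1]]), ncol(rec$data))
  }
  expect_error(band_decompose(eeg_recording(matrix(0, 1, 100), 128, "T7")),
               "wrong rate")
  zb <- band_decompose(eeg_recording(matrix(0, 1, 512), 256, "T7"))
  expect_true(all(zb$bands[[1]] == 0))
})

test_that("db6 decomposition round-trips losslessly", {
  set.seed(1)
  for (n in c(256, 1000, 2561)) {
    x <- rnorm(n)
    expect_lt(max(abs(waverec_db6(wavedec_db6(x, 5)) - x)) / max(abs(x)),
              1e-10)
  }
  # the five bands plus the discarded D1 reconstruction sum back to the input
  x <- rnorm(2560)
  parts <- eegentropy:::cpp_band_reconstruct(x, 5L)
  expect_lt(max(abs(rowSums(parts) - x)), 1e-6 * max(abs(x)))
})

test_that("threshold rule matches the hand-computed worked case", {
  res <- threshold_level(c(rep(0, 9), 10))
  expect_equal(res$threshold, 1 + 2 * sqrt(10), tolerance = 1e-12)
  expect_equal(res$coefficients, c(rep(0, 9), 5))
  # positive constant: threshold equals the value, nothing halved
  res2 <- threshold_level(rep(3, 8))
  expect_equal(res2$threshold, 3)
  expect_equal(res2$coefficients, rep(3, 8))
  # no coefficient above threshold leaves input untouched
  set.seed(2)
  cj <- rnorm(50)
  res3 <- threshold_level(cj)
  if (all(abs(cj) <= res3$threshold)) {
    expect_identical(res3$coefficients, cj)
  }
  # never increases any magnitude
  expect_true(all(abs(res3$coefficients) <= abs(cj) + 1e-15))
  expect_error(threshold_level(3), "insufficient")
})

test_that("artifact removal shrinks transients and spares clean signal", {
  t <- seq(0, 8 - 1e-9, by = 1 / 256)
  # a smooth slow drift keeps every coefficient below threshold: untouched
  drift <- 10 + 3 * t
  bd0 <- band_decompose(eeg_recording(matrix(drift, 1), 256, "T7"))
  cor1 <- remove_artifacts(bd0)
  expect_true(cor1$artifact_corrected)
  expect_lt(max(abs(cor1$bands[[1]]["delta", ] - bd0$bands[[1]]["delta", ])) /
              max(abs(bd0$bands[[1]]["delta", ])), 1e-3)

  # inject a blink-like transient; its peak must strictly shrink
  clean <- sin(2 * pi * 6 * t)
  blink <- clean
  idx <- 900:1000
  blink[idx] <- blink[idx] + 40 * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 101)))
  bd2 <- band_decompose(eeg_recording(matrix(blink, 1), 256, "T7"))
  before <- max(abs(bd2$bands[[1]]["delta", ]))
  cor2 <- remove_artifacts(bd2)
  after <- max(abs(cor2$bands[[1]]["delta", ]))
  expect_lt(after, before)
  # a second pass changes the signal less than the first did
  cor3 <- remove_artifacts(cor2)
  d1 <- max(abs(cor2$bands[[1]]["delta", ] - bd2$bands[[1]]["delta", ]))
  d2 <- max(abs(cor3$bands[[1]]["delta", ] - cor2$bands[[1]]["delta", ]))
  expect_lt(d2, d1)
})
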