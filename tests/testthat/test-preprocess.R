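test_that("sound energy is the plain sum of squared samples", {
  expect_equal(sound_energy(waveform(rep(0, 50))), 0)
  expect_equal(sound_energy(waveform(rep(1, 100))), 100)
  set.seed(101)
  x <- runif(8000, -1, 1)
  acc <- 0
  for (v in x) acc <- acc + v * v
  expect_equal(sound_energy(waveform(x)), acc, tolerance = 1e-12)
  expect_error(waveform(numeric(0)), "at least one sample")
})

test_that("activity gate passes loud clips and the exact threshold", {
  silence <- waveform(rep(1e-4, 8000))
  expect_false(activity_gate(silence))
  x <- runif(8000, -1, 1)
  loud <- waveform(x * sqrt(200 / sum(x^2)))   # cough/scream-level energy
  expect_true(activity_gate(loud))
  exact <- waveform(x * sqrt(40 / sum(x^2)))
  expect_true(activity_gate(exact))
  expect_error(activity_gate(loud, threshold = -1), "non-negative")
})

test_that("hamming window matches its defining formula", {
  expect_equal(hamming_window(3), c(0.08, 1, 0.08))
  L <- 256
  w <- hamming_window(L)
  manual <- sapply(0:(L - 1), function(n) 0.54 - 0.46 * cos(2 * pi * n / (L - 1)))
  expect_equal(w, manual, tolerance = 1e-15)
  expect_equal(w, rev(w))
  expect_error(hamming_window(0), "integer >= 1")
})

test_that("framing slices and windows exactly, dropping the partial tail", {
  w <- waveform(1:10)
  fm <- frame_signal(w, L = 4, inc = 2, window = rep(1, 4))
  expect_equal(nrow(fm$frames), 4)
  expect_equal(fm$frames[2, ], c(3, 4, 5, 6))
  expect_true(all(frame_signal(w, 4, 2, rep(0, 4))$frames == 0))
  set.seed(7)
  x <- rnorm(4000)
  win <- hamming_window(256)
  fm2 <- frame_signal(waveform(x), 256, 128, win)
  expect_equal(fm2$frames, naive_frames(x, 256, 128, win), tolerance = 1e-14)
  expect_error(frame_signal(waveform(1:100), L = 256), "shorter")
})

test_that("non-overlapping rectangular frames reconstruct the input", {
  set.seed(8)
  x <- rnorm(1000)
  fm <- frame_signal(waveform(x), 64, 64, rep(1, 64))
  flat <- as.vector(t(fm$frames))
  expect_identical(flat, x[seq_along(flat)])
})

test_that("short-time energy is the per-frame sum of squares", {
  z <- frame_signal(waveform(rep(0, 1000)), 100, 50, rep(1, 100))
  expect_equal(short_time_energy(z), rep(0, nrow(z$frames)))
  win <- hamming_window(256)
  fm <- frame_signal(waveform(win), 256, 256, rep(1, 256))
  expect_equal(short_time_energy(fm), sum(win^2))
  set.seed(9)
  w <- waveform(rnorm(2000))
  w2 <- waveform(2 * w$samples)
  fm1 <- frame_signal(w, 256, 128)
  fm2 <- frame_signal(w2, 256, 128)
  expect_equal(short_time_energy(fm2), 4 * short_time_energy(fm1))
})

test_that("zero-crossing rate counts sign changes with sgn(0) = +1", {
  fm_pos <- frame_signal(waveform(rep(0.5, 64)), 32, 32, rep(1, 32))
  expect_equal(zero_crossing_rate(fm_pos), rep(0, 2))
  alt <- rep(c(1, -1), 32)
  fm_alt <- frame_signal(waveform(alt), 64, 64, rep(1, 64))
  expect_equal(zero_crossing_rate(fm_alt), 63)
  set.seed(10)
  x <- rnorm(512)
  fm <- frame_signal(waveform(x), 128, 64, rep(1, 128))
  brute <- apply(fm$frames, 1, function(fr) {
    s <- ifelse(fr >= 0, 1, -1)
    count <- 0
    for (n in 2:length(s)) count <- count + abs(s[n] - s[n - 1])
    count / 2
  })
  expect_equal(zero_crossing_rate(fm), brute)
  expect_equal(zero_crossing_rate(fm),
               zero_crossing_rate(frame_signal(waveform(3.7 * x), 128, 64,
                                               rep(1, 128))))
})

test_that("double-threshold detection anchors on the high-energy run", {
  energy <- c(rep(0.01, 19), rep(1, 21), rep(0.01, 20))
  zcr <- rep(10, 60)
  ep <- detect_endpoints(energy, zcr, high_energy = 0.5, low_energy = 0.05,
                         zcr_thresh = 100, min_voiced_frames = 3)
  expect_true(ep$valid)
  expect_gte(ep$start_frame, 18); expect_lte(ep$start_frame, 22)
  expect_gte(ep$end_frame, 38); expect_lte(ep$end_frame, 42)

  ep2 <- detect_endpoints(rep(0.01, 50), rep(5, 50), high_energy = 0.5,
                          low_energy = 0.05, zcr_thresh = 100)
  expect_false(ep2$valid)

  ep3 <- detect_endpoints(rep(1, 50), rep(5, 50), high_energy = 0.5,
                          low_energy = 0.05, zcr_thresh = 100)
  expect_equal(c(ep3$start_frame, ep3$end_frame), c(1, 50))
  expect_error(detect_endpoints(1:5, 1:4), "same length")
})

test_that("low-energy extension pulls endpoints into onset and tail", {
  energy <- c(rep(0.001, 10), 0.2, 0.3, rep(1, 10), 0.3, 0.2, rep(0.001, 10))
  zcr <- rep(0, length(energy))
  ep <- detect_endpoints(energy, zcr, high_energy = 0.9, low_energy = 0.1,
                         zcr_thresh = 10, min_voiced_frames = 3)
  expect_equal(ep$start_frame, 11)   # extended back through 0.3 and 0.2
  expect_equal(ep$end_frame, 24)
})
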