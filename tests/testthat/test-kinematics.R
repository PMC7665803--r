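test_that("a pure 12-Hz cosine decomposes to its amplitude, offset and phase", {
  t <- seq(0, 2, by = 1e-3)
  ks <- hilbert_decompose(70 + 15 * cos(2 * pi * 12 * t))
  i <- 300:1700  # away from filter edges
  expect_equal(mean(ks$amplitude[i]), 15, tolerance = 0.5 / 15)
  expect_lt(max(abs(ks$amplitude[i] - 15)), 0.5)
  expect_equal(mean(ks$midpoint[i]), 70, tolerance = 0.5 / 70)
  # phase is 0 at protraction maxima of the band-passed signal
  pk <- which(diff(sign(diff(ks$bandpassed))) == -2) + 1L
  pk <- pk[pk > 300 & pk < 1700]
  expect_lt(max(abs(ks$phase[pk])), 0.15)
  expect_true(all(ks$whisking[i]))
})

test_that("a constant angle gives zero amplitude and no whisking", {
  ks <- hilbert_decompose(rep(70, 1500))
  expect_lt(max(ks$amplitude), 1e-6)
  expect_true(all(is.finite(ks$phase)))
  expect_false(any(ks$whisking))
})

test_that("instantaneous frequency tracks a 6-25 Hz chirp within 5%", {
  t <- seq(0, 4, by = 1e-3)
  k <- (25 - 6) / 4
  ks <- hilbert_decompose(70 + 12 * cos(2 * pi * (6 * t + k * t^2 / 2)))
  dph <- atan2(sin(diff(ks$phase)), cos(diff(ks$phase)))
  inst <- dph * 1000 / (2 * pi)
  i <- 500:3500
  f_true <- 6 + k * t[i]
  expect_lt(max(abs(inst[i] - f_true) / f_true), 0.05)
})

test_that("decomposition is idempotent on the band-passed signal", {
  wt <- simulate_whisking(whisking_model(), 5, seed = 4)
  ks1 <- hilbert_decompose(wt$angle)
  ks2 <- hilbert_decompose(ks1$bandpassed)
  i <- 500:4500
  expect_equal(ks2$amplitude[i], ks1$amplitude[i], tolerance = 0.02)
  expect_lt(stats::median(abs(
    atan2(sin(ks2$phase[i] - ks1$phase[i]),
          cos(ks2$phase[i] - ks1$phase[i])))), 0.05)
})

test_that("amplitude envelope bounds the band-passed signal pointwise", {
  wt <- simulate_whisking(whisking_model(), 5, seed = 8)
  ks <- hilbert_decompose(wt$angle)
  expect_true(all(ks$amplitude^2 >= ks$bandpassed^2 - 1e-8))
  expect_true(all(ks$amplitude >= 0))
})

test_that("whisking segmentation is monotone in the threshold", {
  wt <- simulate_whisking(whisking_model(), 8, seed = 3)
  ks <- hilbert_decompose(wt$angle)
  w5 <- segment_whisking(ks, amp_threshold = 5)$whisking
  w8 <- segment_whisking(ks, amp_threshold = 8)$whisking
  expect_true(all(which(w8) %in% which(w5)))
})

test_that("segmentation recovers generated bout epochs (Jaccard >= 0.95)", {
  wt <- simulate_whisking(whisking_model(), 20, seed = 9)
  ks <- hilbert_decompose(wt$angle)
  truth <- wt$envelope > 5
  jac <- sum(truth & ks$whisking) / sum(truth | ks$whisking)
  expect_gte(jac, 0.95)
  # a 300-ms constant bout yields a single epoch of about that length
  ang <- rep(70, 1200)
  ang[450:749] <- 70 + 15 * cos(2 * pi * 16 * seq(0, 0.299, 1e-3))
  ep <- whisking_epochs(hilbert_decompose(ang))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$end_ms - ep$start_ms, 300, tolerance = 0.15)
  # amplitude 3 degrees never crosses the 5-degree threshold
  low <- hilbert_decompose(70 + 3 * cos(2 * pi * 16 * seq(0, 1.2, 1e-3)))
  expect_false(any(low$whisking))
})

test_that("whisking-rate comparison recovers a gain-2 neuron and is quiet on nulls", {
  nr <- ground_truth_neuron(baseline_rate = 6, whisking_gain = 2,
                            touch_responsive = FALSE)
  b <- simulate_session(nr, n_trials = 40, seed = 21)
  wr <- whisking_rate_comparison(b)
  expect_true(wr$defined)
  expect_true(wr$modulated)
  expect_equal(wr$rate_whisking / wr$rate_quiet, 2, tolerance = 0.25)
  # homogeneous neuron: modulation call is rare at alpha = 0.01
  nr0 <- ground_truth_neuron(baseline_rate = 6, whisking_gain = 1,
                             touch_responsive = FALSE)
  fp <- 0
  for (s in 1:40) {
    fp <- fp + whisking_rate_comparison(
      simulate_session(nr0, n_trials = 8, seed = 400 + s))$modulated
  }
  expect_lte(fp / 40, 0.05)
})

test_that("a spikeless session gives zero rates and no modulation call", {
  nr <- ground_truth_neuron(baseline_rate = 0, touch_responsive = FALSE)
  b <- simulate_session(nr, n_trials = 5, seed = 2)
  wr <- whisking_rate_comparison(b)
  expect_equal(wr$rate_whisking, 0)
  expect_equal(wr$rate_quiet, 0)
  expect_false(wr$modulated)
})
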