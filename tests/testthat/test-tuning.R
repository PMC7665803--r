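test_that("400 touches partition into 20 bins of exactly 20", {
  d <- make_tuning_samples(400, seed = 1)
  tc <- build_tuning_curve(d, stimulus, count)
  expect_equal(nrow(tc), 20L)
  expect_true(all(tc$occupancy == 20))
  expect_true(all(diff(tc$stimulus) > 0))
  # equal occupancy holds for awkward sizes too
  for (n in c(41, 137, 457)) {
    tci <- build_tuning_curve(make_tuning_samples(n, seed = n), stimulus, count)
    expect_lte(diff(range(tci$occupancy)), 1)
  }
  expect_error(build_tuning_curve(make_tuning_samples(39), stimulus, count),
               "40 samples")
})

test_that("a constant response gives a flat curve with zero modulation", {
  d <- tibble::tibble(x = runif(100), y = 5)
  tc <- build_tuning_curve(d, x, y)
  md <- modulation_depths(tc)
  expect_equal(md$abs_mod_depth, 0, tolerance = 1e-10)
  tc <- test_tuning(tc)
  expect_false(glance(tc)$is_tuned)
})

test_that("modulation depths follow the max/min formulas", {
  # identity smoother so the curve carries exactly the supplied values
  d <- tibble::tibble(x = rep(1:20, each = 2), y = rep(c(4, rep(8, 18), 12), each = 2))
  tc <- build_tuning_curve(d, x, y, smoother = function(x, y) y)
  md <- modulation_depths(tc)
  expect_equal(md$abs_mod_depth, 8)
  expect_equal(md$mod_depth, 0.5)
  z <- build_tuning_curve(tibble::tibble(x = rep(1:20, 2), y = 0), x, y,
                          smoother = function(x, y) y)
  mz <- modulation_depths(z)
  expect_equal(mz$abs_mod_depth, 0)
  expect_true(mz$undefined)
})

test_that("the two-step shuffle test is calibrated and powerful", {
  # type-I on label-free noise
  fp <- 0
  for (i in 1:200) {
    d <- withr::with_seed(3000 + i,
                          tibble::tibble(x = runif(400), y = rpois(400, 1)))
    fp <- fp + glance(test_tuning(build_tuning_curve(d, x, y),
                                  seed = i))$is_tuned
  }
  expect_lte(fp / 200, 0.015 + 0.02)  # binomial slack at n = 200
  # power on strong tuning
  hits <- 0
  for (i in 1:20) {
    d <- make_tuning_samples(400, pref = 5, sdev = 1.5, peak = 2,
                             seed = 400 + i)
    hits <- hits + glance(test_tuning(build_tuning_curve(d, stimulus, count),
                                      seed = i))$is_tuned
  }
  expect_gte(hits / 20, 0.95)
  # identical responses: F undefined, not tuned
  d0 <- tibble::tibble(x = runif(100), y = 1)
  expect_false(glance(test_tuning(build_tuning_curve(d0, x, y)))$is_tuned)
})

test_that("preference and width recover the generating Gaussian", {
  d <- make_tuning_samples(2000, pref = 5, sdev = 1, peak = 3, seed = 5)
  tc <- build_tuning_curve(d, stimulus, count) |>
    test_tuning(seed = 1) |> tuning_width()
  w <- attr(tc, "width")
  expect_equal(w$preference, 5, tolerance = 0.1)
  expect_equal(w$half_max_width, 2 * sqrt(2 * log(2)) * 1, tolerance = 0.3 / 2.355)
  expect_false(any(is.na(w$width_bins)))
  # needle tuning: immediate neighbours differ from the peak
  dn <- withr::with_seed(6, tibble::tibble(
    x = rep(1:20, each = 20) + runif(400, -0.3, 0.3)))
  dn$y <- withr::with_seed(7, rnorm(400, ifelse(round(dn$x) == 10, 10, 1), 0.5))
  tn <- build_tuning_curve(dn, x, y) |> test_tuning(seed = 2) |> tuning_width()
  expect_equal(attr(tn, "width")$width_bins, c(9L, 11L))
  # flat curve: no width defined
  df <- tibble::tibble(x = runif(100), y = rnorm(100, 5, 0.1))
  tf <- build_tuning_curve(df, x, y) |> test_tuning(seed = 3) |> tuning_width()
  expect_true(all(is.na(attr(tf, "width")$width_bins)))
})

test_that("modulation depth recovery is within 10% of the generator", {
  d <- make_tuning_samples(4000, pref = 5, sdev = 1.5, peak = 3, seed = 9)
  tc <- build_tuning_curve(d, stimulus, count)
  md <- modulation_depths(tc)
  expect_equal(md$abs_mod_depth, 3, tolerance = 0.1)
})

test_that("covariate stratification separates scaled responses, not nulls", {
  withr::with_seed(21, {
    x <- runif(800, 0, 10)
    cv <- runif(800)
    y_null <- rpois(800, 2)
    y_scaled <- rpois(800, 2 * (0.5 + cv))
  })
  d <- tibble::tibble(x, cv, y_null, y_scaled)
  s0 <- stratified_tuning(d, x, y_null, cv)
  expect_lt(abs(s0$rate_increase), 0.25)
  s1 <- stratified_tuning(d, x, y_scaled, cv)
  expect_gt(s1$rate_increase, 0.3)
  expect_true(all(s1$high$response[order(s1$high$bin)] >=
                    s1$low$response[order(s1$low$bin)] - 1.5))
  expect_error(stratified_tuning(dplyr::mutate(d, cv = 1), x, y_null, cv),
               "constant")
})

test_that("per-bin Fano factors diagnose dispersion", {
  d <- make_tuning_samples(4000, pref = 5, sdev = 2, peak = 2, seed = 31)
  f1 <- fano_per_bin(d, stimulus, count)
  expect_equal(unname(attr(f1, "summary")["mean"]), 1, tolerance = 0.1)
  # deterministic counts: Fano 0
  dd <- tibble::tibble(x = runif(200), k = rep(3, 200))
  expect_true(all(fano_per_bin(dd, x, k)$fano == 0))
  # doubling counts doubles the Fano factor
  d2 <- dplyr::mutate(d, count = 2L * count)
  f2 <- fano_per_bin(d2, stimulus, count)
  expect_equal(unname(attr(f2, "summary")["mean"]), 2, tolerance = 0.15)
})

test_that("whisking tuning respects the 2-Hz evaluation floor", {
  nr <- ground_truth_neuron(baseline_rate = 0.3, touch_responsive = FALSE)
  b <- simulate_session(nr, n_trials = 10, seed = 41)
  expect_message(out <- whisking_tuning_data(b), "not evaluated")
  expect_null(out)
  nr2 <- ground_truth_neuron(baseline_rate = 8, touch_responsive = FALSE)
  b2 <- simulate_session(nr2, n_trials = 10, seed = 42)
  wd <- whisking_tuning_data(b2)
  expect_false(is.null(wd))
  expect_true(all(c("angle", "phase", "amplitude", "midpoint", "velocity")
                  %in% names(wd)))
})
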