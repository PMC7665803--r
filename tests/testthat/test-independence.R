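test_that("overlap statistics reproduce the product rule on known counts", {
  # marginals 54/115 and 42/115 with an observed joint of 22/115
  rec <- tibble::tibble(
    tuned_whisking = rep(c(TRUE, TRUE, FALSE, FALSE), c(22, 32, 20, 41)),
    tuned_touch = rep(c(TRUE, FALSE, TRUE, FALSE), c(22, 32, 20, 41))
  )
  ov <- overlap_statistics(rec)
  expect_equal(ov$p_whisking, 100 * 54 / 115)
  expect_equal(ov$p_touch, 100 * 42 / 115)
  expect_equal(ov$p_cotuned_observed, 100 * 22 / 115)
  expect_equal(ov$p_cotuned_expected, 100 * (54 / 115) * (42 / 115))
  # printed rounded values
  expect_equal(round(ov$p_whisking), 47)
  expect_equal(round(ov$p_cotuned_observed), 19)
  expect_equal(round(ov$p_cotuned_expected), 17)
  # degenerate cases
  all2 <- tibble::tibble(tuned_whisking = rep(TRUE, 10),
                         tuned_touch = rep(TRUE, 10))
  ova <- overlap_statistics(all2)
  expect_equal(ova$p_cotuned_observed, 100)
  expect_equal(ova$p_cotuned_expected, 100)
  expect_error(overlap_statistics(all2[0, ]), "empty")
})

test_that("independent assignment converges to the product (law of large numbers)", {
  rec <- withr::with_seed(5, tibble::tibble(
    tuned_whisking = runif(10000) < 0.47,
    tuned_touch = runif(10000) < 0.36
  ))
  ov <- overlap_statistics(rec)
  expect_lt(abs(ov$p_cotuned_observed - ov$p_cotuned_expected), 1)
  # observed always lies within the Frechet bounds
  lo <- max(0, ov$p_whisking + ov$p_touch - 100)
  hi <- min(ov$p_whisking, ov$p_touch)
  expect_gte(ov$p_cotuned_observed, lo)
  expect_lte(ov$p_cotuned_observed, hi)
})

make_curves <- function(n, rho = c("match", "anti", "none"), seed = 1) {
  rho <- match.arg(rho)
  withr::with_seed(seed, {
    grid <- seq(0, 10, length.out = 20)
    tibble::tibble(
      neuron_id = sprintf("n%02d", 1:n),
      curve_whisking = lapply(1:n, function(i) {
        y <- exp(-(grid - runif(1, 2, 8))^2 / 2) + rnorm(20, 0, 0.05)
        tibble::tibble(stimulus = grid, response = y)
      }),
      curve_touch = vector("list", n)
    ) -> d
    d$curve_touch <- lapply(1:n, function(i) {
      w <- d$curve_whisking[[i]]
      y <- switch(rho,
        match = w$response,
        anti = max(w$response) - w$response,
        none = exp(-(grid - runif(1, 2, 8))^2 / 2) + rnorm(20, 0, 0.05))
      tibble::tibble(stimulus = grid, response = y)
    })
    d
  })
}

test_that("shape correlation separates matched, anti and unrelated curve pairs", {
  m <- shape_correlation_test(make_curves(15, "match", seed = 2),
                              n_shuffles = 200, seed = 3)
  expect_true(all(m$observed$r > 0.98))
  expect_lt(m$p_value, 0.05)
  a <- shape_correlation_test(make_curves(15, "anti", seed = 4),
                              n_shuffles = 200, seed = 5)
  expect_true(all(a$observed$r < -0.98))
  u <- shape_correlation_test(make_curves(30, "none", seed = 6),
                              n_shuffles = 200, seed = 7)
  expect_gt(u$p_value, 0.01)
})

test_that("shuffle re-pairing preserves each marginal curve set exactly", {
  cu <- make_curves(10, "none", seed = 8)
  # re-pairing is a permutation: pooled correlations use every whisking and
  # every touch curve the same number of times per shuffle
  res <- shape_correlation_test(cu, n_shuffles = 50, seed = 9)
  expect_length(res$shuffled, 50 * 10)
  # and each shuffle's correlation multiset is invariant to neuron order
  cu2 <- cu[sample(nrow(cu)), ]
  res2 <- shape_correlation_test(cu2, n_shuffles = 50, seed = 9)
  expect_equal(sort(res2$observed$r), sort(res$observed$r))
})

test_that("non-overlapping supports are skipped with a message", {
  cu <- make_curves(4, "match", seed = 10)
  cu$curve_touch[[2]]$stimulus <- cu$curve_touch[[2]]$stimulus + 100
  expect_message(res <- shape_correlation_test(cu, n_shuffles = 20, seed = 1),
                 "skipping")
  expect_equal(nrow(res$observed), 3)
  expect_equal(res$skipped, "n02")
})

test_that("preference displacement matches closed forms", {
  # identical preferences: all distances 0, r = 1 on jittered data
  same <- tibble::tibble(pref_whisking = c(1, 4, 7, 9),
                         pref_touch = c(1, 4, 7, 9))
  ds <- preference_displacement(same)
  expect_equal(ds$mean, 0)
  expect_equal(ds$pearson_r, 1)
  expect_true(is.na(ds$p_value))  # zero-variance distances: test skipped
  # independent uniforms on a 40-degree range: E|U1 - U2| = range / 3
  ind <- withr::with_seed(11, tibble::tibble(
    pref_whisking = runif(4000, 60, 100),
    pref_touch = runif(4000, 60, 100)
  ))
  di <- preference_displacement(ind)
  expect_equal(di$mean, 40 / 3, tolerance = 0.03)
  expect_lt(abs(di$pearson_r), 0.05)
  expect_lt(di$p_value, 1e-10)
  # circular distance: identical phases give 0; range is [0, pi]
  ph <- withr::with_seed(12, tibble::tibble(
    pref_whisking = runif(100, -pi, pi)))
  ph$pref_touch <- ph$pref_whisking
  expect_equal(preference_displacement(ph, circular = TRUE)$mean, 0)
  ph2 <- withr::with_seed(13, tibble::tibble(
    pref_whisking = runif(500, -pi, pi),
    pref_touch = runif(500, -pi, pi)))
  d2 <- preference_displacement(ph2, circular = TRUE)$distances
  expect_true(all(d2 >= 0 & d2 <= pi))
  # fewer than 3 co-tuned neurons: test skipped
  two <- tibble::tibble(pref_whisking = c(1, 2), pref_touch = c(2, 4))
  expect_true(is.na(preference_displacement(two)$p_value))
})
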