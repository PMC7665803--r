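curve_from_lambda <- function(pref, peak = 2, sdev = 1, n = 400, seed = 1) {
  d <- make_tuning_samples(n, pref = pref, sdev = sdev, peak = peak,
                           seed = seed)
  build_tuning_curve(d, stimulus, count)
}

test_that("the design has the stated geometry and Poisson moments", {
  curves <- lapply(1:5, function(i) curve_from_lambda(2 * i - 1, seed = i))
  des <- build_design(curves, seed = 3)
  expect_equal(dim(des$x), c(2000L, 5L))
  expect_equal(length(des$y), 2000L)
  expect_true(all(table(des$y) == 50))
  expect_true(all(des$x >= 0 & des$x == round(des$x)))
  expect_true(all(des$lambda >= 0))
  expect_equal(des$locations, seq(0.125, 9.875, by = 0.25))
  # constant-lambda column: mean and variance match Poisson moments
  flat <- make_tuning_samples(400, seed = 99)
  flat$count <- withr::with_seed(123, rpois(400, 2))
  cflat <- build_tuning_curve(flat, stimulus, count)
  df <- build_design(list(a = cflat), seed = 5)
  expect_equal(mean(df$x), 2, tolerance = 0.1)
  expect_equal(var(as.numeric(df$x)), 2, tolerance = 0.15)
})

test_that("inclusion criteria exclude sparse or narrow-coverage neurons", {
  good <- curve_from_lambda(5, seed = 1)
  few <- build_tuning_curve(make_tuning_samples(60, seed = 2), stimulus, count)
  narrow_d <- make_tuning_samples(400, pref = 5, seed = 3, range = c(4, 6))
  narrow <- build_tuning_curve(narrow_d, stimulus, count)
  des <- build_design(list(g = good, f = few, n = narrow), seed = 1)
  expect_equal(des$neurons, "g")
  expect_setequal(des$excluded$neuron, c("f", "n"))
  expect_error(build_design(list(f = few), seed = 1), "inclusion")
})

test_that("a silent neuron contributes an all-zero column", {
  z <- make_tuning_samples(400, seed = 4)
  z$count <- 0L
  cz <- build_tuning_curve(z, stimulus, count)
  des <- build_design(list(z = cz, g = curve_from_lambda(5, seed = 6)),
                      seed = 2)
  expect_true(all(des$x[, 1] == 0))
})

test_that("decoder matches the Bayes oracle and its contracts hold", {
  # sharply tuned population tiling the range
  prefs <- seq(0.25, 9.75, length.out = 12)
  curves <- lapply(seq_along(prefs), function(i) {
    curve_from_lambda(prefs[i], peak = 3, sdev = 0.8, seed = 40 + i)
  })
  des <- build_design(curves, seed = 7)
  mod <- fit_decoder(des, n_iter = 2, seed = 8)
  expect_true(all(abs(rowSums(mod$confusion) - 1) < 1e-8))
  res <- resolution_and_neurometric(mod)
  expect_equal(res$resolution$fraction[res$resolution$n_bins == 39], 1)
  expect_true(all(diff(res$resolution$fraction) >= -1e-12))
  bayes <- bayes_location_decoder(des$lambda, mod$x_test)
  acc_bayes <- mean(bayes == mod$y_test)
  expect_lte(abs(mod$accuracy_iter[1] - acc_bayes), 0.05)
  # decoder never beats the exact-likelihood oracle by more than MC error
  expect_lte(mod$accuracy_iter[1], acc_bayes + 0.05)
  # neuron column order does not change oracle accuracy
  p <- sample(ncol(des$lambda))
  bayes_p <- bayes_location_decoder(des$lambda[, p], mod$x_test[, p])
  expect_identical(bayes_p, bayes)
})

test_that("an uninformative neuron decodes at chance", {
  flat <- make_tuning_samples(400, seed = 77)
  flat$count <- withr::with_seed(124, rpois(400, 2))
  cflat <- build_tuning_curve(flat, stimulus, count)
  des <- build_design(list(a = cflat), seed = 9)
  mod <- fit_decoder(des, n_iter = 2, seed = 10)
  expect_lte(mod$accuracy, 2.5 / 40)
})

test_that("coefficient subsetting reproduces the full model and degrades gracefully", {
  prefs <- c(1, 3, 5, 7, 9)
  curves <- lapply(seq_along(prefs), function(i) {
    curve_from_lambda(prefs[i], peak = 3, sdev = 1, seed = 60 + i)
  })
  des <- build_design(curves, seed = 11)
  mod <- fit_decoder(des, n_iter = 2, seed = 12)
  # identity subset: same predictions as the fitted model's first iteration
  pred <- whisklocate:::predict_from_coef(mod$a0, mod$beta, mod$x_test)
  expect_equal(mean(pred == mod$y_test), mod$accuracy_iter[1])
  ss <- subsample_population(mod, c(1, 3, 5), n_draws = 60, seed = 13)
  expect_true(all(diff(ss$accuracy_mean) > 0))
  expect_true(all(diff(ss$resolution2_mean) > 0))
  expect_error(subsample_population(mod, 0), "positive")
  # fixed seed reproduces the curve
  ss2 <- subsample_population(mod, c(1, 3, 5), n_draws = 60, seed = 13)
  expect_identical(ss, ss2)
})

test_that("resolution and neurometric readouts follow closed forms", {
  k <- 40
  mk_model <- function(confusion) {
    structure(list(confusion = confusion, locations = seq(0.125, 9.875, 0.25),
                   bin_mm = 0.25, go_bins = 1:20, neurons = "x",
                   accuracy = NA_real_),
              class = "decoder_model")
  }
  ident <- mk_model(diag(k))
  r <- resolution_and_neurometric(ident)
  expect_equal(r$resolution$fraction[1], 1)
  expect_equal(r$neurometric$lick_prob, rep(c(1, 0), each = 20))
  expect_equal(r$neurometric$lick, rep(c(TRUE, FALSE), each = 20))
  unif <- mk_model(matrix(1 / k, k, k))
  ru <- resolution_and_neurometric(unif)
  # interior rows: fraction within n bins is (2n+1)/k; row-averaged value
  # is smaller because edge rows truncate, so check n = 0 exactly
  expect_equal(ru$resolution$fraction[1], 1 / k)
  expect_equal(ru$neurometric$lick_prob, rep(0.5, k))
})

test_that("psychometric comparison flags only genuinely different locations", {
  locs <- seq(0.125, 9.875, 0.25)
  psych <- tibble::tibble(location_mm = locs,
                          mean_lick_prob = 1 / (1 + exp((locs - 5))),
                          sd = 0.08, n = 15)
  draws <- withr::with_seed(3, tibble::tibble(
    location_mm = rep(locs, 40),
    lick_prob = rep(psych$mean_lick_prob, 40) + rnorm(40 * 40, 0, 0.08)
  ))
  same <- compare_to_psychometric(draws, psych)
  expect_lte(mean(same$significant), 0.15)
  shifted <- dplyr::mutate(draws, lick_prob = lick_prob + 0.4)
  diff <- compare_to_psychometric(shifted, psych)
  expect_gte(mean(diff$significant), 0.9)
  coarse <- psych[seq(1, 40, 4), ]
  expect_warning(compare_to_psychometric(draws, coarse), "interpolat")
})
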