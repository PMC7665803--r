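make_results <- function(n, p_touch = 0.4, p_loc = 0.8, p_angle = 0.45,
                         p_phase = 0.35, p_silent = 0.1, seed = 1,
                         condition = NULL) {
  withr::with_seed(seed, {
    touch <- runif(n) < p_touch
    tibble::tibble(
      neuron_id = sprintf("u%03d", 1:n),
      condition = condition %||% sample(c("naive", "trained"), n, TRUE,
                                        prob = c(0.74, 0.26)),
      depth = runif(n, 600, 950),
      n_spikes = ifelse(runif(n) < p_silent, 0L, rpois(n, 500) + 1L),
      touch_unit = touch,
      location_tuned = touch & runif(n) < p_loc,
      angle_tuned_whisking = runif(n) < p_angle,
      phase_tuned_whisking = runif(n) < p_phase
    )
  })
}

test_that("ledger partitions are consistent and silent units excluded", {
  res <- make_results(200, seed = 3)
  led <- classify_population(res)
  nn <- led$neurons
  expect_true(all(!nn$location_tuned | nn$touch_unit))
  expect_true(all(!nn$co_tuned_angle |
                    (nn$angle_tuned_whisking & nn$location_tuned)))
  # silent neurons carry no tuned flags and are excluded from denominators
  expect_true(all(!nn$touch_unit[!nn$active]))
  all_props <- led$proportions[led$proportions$condition == "all", ]
  expect_true(all(all_props$n_active == sum(nn$active)))
  expect_true(all(all_props$proportion >= 0 & all_props$proportion <= 1))
  # tuned + untuned partitions the active population
  act <- nn[nn$active, ]
  expect_equal(sum(act$touch_unit) + sum(!act$touch_unit), nrow(act))
})

test_that("a generator-tuned fraction is recovered within binomial error", {
  res <- make_results(400, p_angle = 0.4, seed = 5)
  led <- classify_population(res)
  p <- led$proportions
  phat <- p$proportion[p$condition == "all" & p$flag == "angle_tuned_whisking"]
  n_act <- p$n_active[p$condition == "all"][1]
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / n_act))
})

test_that("condition comparison mirrors the naive/trained split", {
  res <- dplyr::bind_rows(
    make_results(85, seed = 7, condition = "naive"),
    make_results(30, seed = 8, condition = "trained")
  )
  res$neuron_id <- sprintf("u%03d", seq_len(nrow(res)))
  led <- classify_population(res)
  cc <- led$condition_comparison
  expect_setequal(cc$condition, c("naive", "trained"))
  expect_true(all(cc$n_location <= cc$n_touch))
  expect_true(all(is.na(cc$prop_location_of_touch) |
                    (cc$prop_location_of_touch >= 0 &
                       cc$prop_location_of_touch <= 1)))
})

test_that("single neurons and missing stages are handled", {
  one <- make_results(1, p_silent = 0, seed = 9)
  led <- classify_population(one)
  expect_equal(nrow(led$neurons), 1L)
  expect_error(classify_population(one[, -4]), "missing stage")
  # location tuning without touch responsiveness is coerced with a warning
  bad <- make_results(5, seed = 10)
  bad$touch_unit <- FALSE
  bad$location_tuned <- TRUE
  bad$n_spikes <- 10L
  expect_warning(ledb <- classify_population(bad), "coercing")
  expect_true(all(!ledb$neurons$location_tuned))
})

test_that("session analysis classifies a strongly tuned synthetic neuron", {
  # touch response well above the whisking-driven baseline peaks, so the
  # window detector's baseline band is cleanly exceeded
  nr <- ground_truth_neuron(baseline_rate = 4, whisking_gain = 1.2,
                            angle_pref = 76, angle_kappa = 7,
                            location_pref = 4, location_sd = 1,
                            peak_touch_spikes = 3)
  b <- simulate_session(nr, n_trials = 60, seed = 33)
  out <- analyze_session(b, n_shuffles = 300, seed = 2)
  expect_true(out$row$touch_unit)
  expect_true(out$row$location_tuned)
  expect_equal(out$row$location_pref, 4, tolerance = 0.15)
  expect_s3_class(out$location_curve, "tuning_curve")
})
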