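#' Classify a population of analysed neurons
#'
#' Assembles the per-neuron classification ledger from stage outputs:
#' active (at least one spike in the session), touch unit, location
#' tuned, whisking angle/phase tuned, co-tuned; enforces partition
#' consistency (location tuning is only defined for touch units; tuned
#' proportions are over active neurons) and tabulates proportions overall
#' and split by training condition.
#'
#' @param results tibble with one row per neuron: `neuron_id`,
#'   `condition`, `depth`, `n_spikes`, and logical columns
#'   `touch_unit`, `location_tuned`, `angle_tuned_whisking`,
#'   `phase_tuned_whisking` (NA treated as `FALSE`).
#' @return object of class `population_ledger`: list with `neurons` (the
#'   augmented per-neuron tibble), `proportions` (long tibble of counts
#'   and proportions by condition and overall), and
#'   `condition_comparison` (touch-unit and location-tuned-of-touch
#'   fractions per condition).
#' @export
classify_population <- function(results) {
  need <- c("neuron_id", "condition", "n_spikes", "touch_unit",
            "location_tuned", "angle_tuned_whisking", "phase_tuned_whisking")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort(paste0("missing stage outputs for columns: ",
                 paste(miss, collapse = ", ")))
  }
  lg <- function(v) ifelse(is.na(v), FALSE, as.logical(v))
  neurons <- results |>
    mutate(
      active = .data$n_spikes > 0,
      touch_unit = lg(.data$touch_unit) & .data$n_spikes > 0,
      location_tuned = lg(.data$location_tuned) & .data$n_spikes > 0,
      angle_tuned_whisking = lg(.data$angle_tuned_whisking) & .data$n_spikes > 0,
      phase_tuned_whisking = lg(.data$phase_tuned_whisking) & .data$n_spikes > 0
    )
  if (any(neurons$location_tuned & !neurons$touch_unit)) {
    warn("location_tuned without touch_unit; coercing to FALSE (location tuning is defined on touch units).")
    neurons$location_tuned <- neurons$location_tuned & neurons$touch_unit
  }
  neurons <- mutate(
    neurons,
    co_tuned_angle = .data$angle_tuned_whisking & .data$touch_unit &
      .data$location_tuned
  )
  act <- filter(neurons, .data$active)
  prop_tbl <- function(df, label) {
    flags <- c("touch_unit", "location_tuned", "angle_tuned_whisking",
               "phase_tuned_whisking", "co_tuned_angle")
    bind_rows(lapply(flags, function(f) {
      tibble(condition = label, flag = f, n = sum(df[[f]]),
             n_active = nrow(df),
             proportion = if (nrow(df)) sum(df[[f]]) / nrow(df) else NA_real_)
    }))
  }
  proportions <- bind_rows(
    prop_tbl(act, "all"),
    bind_rows(lapply(split(act, act$condition), function(d) {
      prop_tbl(d, d$condition[1])
    }))
  )
  cc <- act |>
    group_by(.data$condition) |>
    summarise(
      n_active = dplyr::n(),
      n_touch = sum(.data$touch_unit),
      n_location = sum(.data$location_tuned),
      prop_touch = .data$n_touch / .data$n_active,
      prop_location_of_touch = ifelse(.data$n_touch > 0,
                                      .data$n_location / .data$n_touch,
                                      NA_real_),
      .groups = "drop"
    )
  structure(list(neurons = neurons, proportions = proportions,
                 condition_comparison = cc),
            class = "population_ledger")
}

#' @exportS3Method base::print
print.population_ledger <- function(x, ...) {
  act <- sum(x$neurons$active)
  cat(sprintf("<population_ledger: %d neurons (%d active, %d silent)>\n",
              nrow(x$neurons), act, nrow(x$neurons) - act))
  print(x$proportions[x$proportions$condition == "all", ])
  invisible(x)
}

#' Run the full single-session analysis chain
#'
#' Convenience wrapper: kinematics, whisking-rate comparison, touch
#' window detection, touch summary, location tuning (pole location, spike
#' counts) and free-whisking angle tuning, returning one classification
#' row per neuron plus the intermediate objects.
#'
#' @param bundle a `session_bundle`.
#' @param n_shuffles permutations for [test_tuning()].
#' @param seed seed for the tuning permutation tests.
#' @param neuron_id identifier for the output row.
#' @return list: `row` (one-row classification tibble), `profile`,
#'   `location_curve`, `whisking_curve` (possibly `NULL`), `summary`.
#' @export
analyze_session <- function(bundle, n_shuffles = 1000, seed = 1,
                            neuron_id = bundle$meta$session_id) {
  kin <- session_kinematics(bundle)
  profile <- tryCatch(detect_touch_window(bundle),
                      error = function(e) NULL)
  smry <- if (!is.null(profile)) {
    touch_summary(bundle, profile, kin = kin)
  } else NULL
  is_touch <- isTRUE(profile$is_touch_unit)
  loc_curve <- NULL
  loc_tuned <- FALSE
  loc_pref <- NA_real_
  if (is_touch) {
    td <- touch_tuning_data(bundle, profile)
    if (nrow(td) >= 40) {
      loc_curve <- build_tuning_curve(td, pole_location_mm, rate_hz,
                                      stimulus_name = "pole_location_mm") |>
        test_tuning(n_shuffles = n_shuffles, seed = seed) |>
        tuning_width()
      loc_tuned <- glance(loc_curve)$is_tuned
      loc_pref <- attr(loc_curve, "width")$preference
    }
  }
  wd <- whisking_tuning_data(bundle, profile, kin = kin)
  whisk_curve <- NULL
  angle_tuned <- FALSE
  phase_tuned <- FALSE
  angle_pref <- NA_real_
  if (!is.null(wd) && nrow(wd) >= 40) {
    whisk_curve <- build_tuning_curve(wd, angle, rate_hz,
                                      stimulus_name = "angle") |>
      test_tuning(n_shuffles = n_shuffles, seed = seed + 1) |>
      tuning_width()
    angle_tuned <- glance(whisk_curve)$is_tuned
    angle_pref <- attr(whisk_curve, "width")$preference
    ph_curve <- build_tuning_curve(wd, phase, rate_hz,
                                   stimulus_name = "phase") |>
      test_tuning(n_shuffles = n_shuffles, seed = seed + 2)
    phase_tuned <- glance(ph_curve)$is_tuned
  }
  row <- tibble(
    neuron_id = neuron_id,
    condition = bundle$meta$condition,
    depth = bundle$meta$neuron_depth,
    n_spikes = nrow(bundle$spikes),
    touch_unit = is_touch,
    location_tuned = loc_tuned,
    angle_tuned_whisking = angle_tuned,
    phase_tuned_whisking = phase_tuned,
    location_pref = loc_pref,
    angle_pref_whisking = angle_pref
  )
  list(row = row, profile = profile, location_curve = loc_curve,
       whisking_curve = whisk_curve, summary = smry)
}
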