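# broom-style tidiers for the package's result objects.

#' Tidy a tuning curve into its per-bin table
#'
#' @param x a `tuning_curve`.
#' @param ... unused.
#' @return tibble `bin`, `stimulus`, `response`, `occupancy`, `smoothed`.
#' @export
tidy.tuning_curve <- function(x, ...) {
  as_tibble(unclass(x)[c("bin", "stimulus", "response", "occupancy",
                         "smoothed")])
}

#' One-row summary of a tuning curve
#'
#' @param x a `tuning_curve` (optionally after [test_tuning()] and
#'   [tuning_width()]).
#' @param ... unused.
#' @return tibble with `stimulus_name`, `n_bins`, `n_samples`,
#'   `is_tuned`, `F_observed`, `p_anova`, `F_shuffle_95`, `preference`,
#'   `width_lo_bin`, `width_hi_bin`, `half_max_width`, `abs_mod_depth`,
#'   `mod_depth`.
#' @export
glance.tuning_curve <- function(x, ...) {
  test <- attr(x, "test") %||% list(is_tuned = NA, F_observed = NA_real_,
                                    p_anova = NA_real_,
                                    F_shuffle_95 = NA_real_)
  width <- attr(x, "width") %||% list(
    preference = x$stimulus[which.max(x$smoothed)],
    width_bins = c(NA_integer_, NA_integer_), half_max_width = NA_real_)
  md <- modulation_depths(x)
  tibble(
    stimulus_name = attr(x, "stimulus_name") %||% NA_character_,
    n_bins = nrow(x),
    n_samples = nrow(attr(x, "samples")),
    is_tuned = test$is_tuned,
    F_observed = test$F_observed,
    p_anova = test$p_anova,
    F_shuffle_95 = test$F_shuffle_95,
    preference = width$preference,
    width_lo_bin = width$width_bins[1],
    width_hi_bin = width$width_bins[2],
    half_max_width = width$half_max_width,
    abs_mod_depth = md$abs_mod_depth,
    mod_depth = md$mod_depth
  )
}

#' Tidy a touch profile into its PSTH table
#'
#' @param x a `touch_profile`.
#' @param ... unused.
#' @return tibble `time_ms`, `rate`, `smoothed`.
#' @export
tidy.touch_profile <- function(x, ...) {
  as_tibble(x$psth)
}

#' One-row summary of a touch profile
#'
#' @param x a `touch_profile`.
#' @param ... unused.
#' @return tibble with baseline, window, latency, duration and response
#'   statistics.
#' @export
glance.touch_profile <- function(x, ...) {
  tibble(
    n_touches = x$n_touches,
    baseline_mean = x$baseline_mean,
    baseline_ci_lo = x$baseline_ci95[1],
    baseline_ci_hi = x$baseline_ci95[2],
    window_start = if (is.null(x$window)) NA_real_ else x$window[1],
    window_end = if (is.null(x$window)) NA_real_ else x$window[2],
    latency = x$latency,
    duration = x$duration,
    mean_window_rate = x$mean_window_rate,
    spikes_per_touch = x$spikes_per_touch,
    response_probability = x$response_probability,
    is_touch_unit = x$is_touch_unit
  )
}

#' Tidy a decoder model into the long confusion matrix
#'
#' @param x a `decoder_model`.
#' @param ... unused.
#' @return tibble `true_mm`, `predicted_mm`, `probability`.
#' @export
tidy.decoder_model <- function(x, ...) {
  k <- length(x$locations)
  tibble(
    true_mm = rep(x$locations, times = k),
    predicted_mm = rep(x$locations, each = k),
    probability = as.numeric(x$confusion)
  )
}

#' One-row summary of a decoder model
#'
#' @param x a `decoder_model`.
#' @param ... unused.
#' @return tibble `n_neurons`, `n_bins`, `accuracy`, `accuracy_sd`,
#'   `resolution_half_mm` (fraction within 2 bins, i.e. 0.5 mm).
#' @export
glance.decoder_model <- function(x, ...) {
  res <- resolution_curve(x$confusion)
  tibble(
    n_neurons = length(x$neurons),
    n_bins = length(x$locations),
    accuracy = x$accuracy,
    accuracy_sd = x$accuracy_sd,
    resolution_half_mm = res$fraction[res$n_bins == 2]
  )
}

#' Tidy a population ledger
#'
#' @param x a `population_ledger`.
#' @param ... unused.
#' @return the proportions table.
#' @export
tidy.population_ledger <- function(x, ...) {
  x$proportions
}
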