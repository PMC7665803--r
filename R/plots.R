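# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile geom_rect geom_hline geom_ribbon labs theme_minimal
#'   scale_fill_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a kinematic decomposition
#'
#' Angle with the slow midpoint overlaid, instantaneous amplitude with
#' the 5-degree whisking threshold, and phase masked to whisking periods.
#'
#' @param object a `kinematic_series`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kinematic_series <- function(object, ...) {
  d <- tidyr::pivot_longer(
    mutate(object,
           phase = ifelse(.data$whisking, .data$phase, NA_real_),
           midpoint_abs = .data$angle - .data$bandpassed),
    c("angle", "amplitude", "phase"),
    names_to = "component", values_to = "value")
  d$component <- factor(d$component, c("angle", "amplitude", "phase"))
  ggplot(d, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    facet_wrap(~component, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL,
         title = "whisker kinematics (angle deg, amplitude deg, phase rad)") +
    theme_minimal()
}

#' Plot a peri-touch response profile
#'
#' Raw and smoothed PSTH with the baseline confidence band and, for touch
#' units, the detected response window.
#'
#' @param object a `touch_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.touch_profile <- function(object, ...) {
  p <- ggplot(object$psth, aes(x = .data$time_ms)) +
    geom_col(aes(y = .data$rate), fill = "grey75", width = 1) +
    geom_line(aes(y = .data$smoothed), colour = "firebrick") +
    geom_hline(yintercept = object$baseline_ci95[2], linetype = "dashed") +
    labs(x = "time from touch onset (ms)", y = "rate (spks/s)",
         title = sprintf("touch PSTH (%d touches)", object$n_touches)) +
    theme_minimal()
  if (!is.null(object$window)) {
    p <- p + ggplot2::annotate("rect", xmin = object$window[1],
                               xmax = object$window[2], ymin = -Inf,
                               ymax = Inf, alpha = 0.15, fill = "goldenrod")
  }
  p
}

#' Plot a tuning curve
#'
#' Bin means with the smoothed curve; the title reports the significance
#' call when [test_tuning()] has been run.
#'
#' @param object a `tuning_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tuning_curve <- function(object, ...) {
  g <- glance(object)
  ttl <- attr(object, "stimulus_name") %||% "stimulus"
  if (!is.na(g$is_tuned)) {
    ttl <- sprintf("%s (%s, F = %.1f)", ttl,
                   if (isTRUE(g$is_tuned)) "tuned" else "not tuned",
                   g$F_observed)
  }
  ggplot(tidy(object), aes(x = .data$stimulus)) +
    geom_point(aes(y = .data$response)) +
    geom_line(aes(y = .data$smoothed), colour = "firebrick") +
    labs(x = attr(object, "stimulus_name"), y = "response",
         title = ttl) +
    theme_minimal()
}

#' Plot a decoder confusion matrix
#'
#' Row-normalised confusion matrix of true versus predicted pole
#' location.
#'
#' @param object a `decoder_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decoder_model <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$predicted_mm, y = .data$true_mm,
             fill = .data$probability)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "predicted location (mm)", y = "true location (mm)",
         title = sprintf("location decoding (accuracy %.1f%%)",
                         100 * object$accuracy)) +
    theme_minimal()
}

#' Plot neurometric against psychometric curves
#'
#' @param neurometric tibble `location_mm`, `lick_prob` (one curve, or
#'   per-draw rows that are averaged).
#' @param psychometric optional tibble `location_mm`, `mean_lick_prob`,
#'   `sd`.
#' @return a ggplot.
#' @export
plot_neurometric <- function(neurometric, psychometric = NULL) {
  nm <- neurometric |>
    group_by(.data$location_mm) |>
    summarise(lick_prob = mean(.data$lick_prob), .groups = "drop")
  p <- ggplot(nm, aes(x = .data$location_mm, y = .data$lick_prob)) +
    geom_line(colour = "firebrick") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = "pole location (mm)", y = "lick probability",
         title = "neurometric curve") +
    theme_minimal()
  if (!is.null(psychometric)) {
    p <- p +
      geom_ribbon(data = psychometric,
                  aes(x = .data$location_mm,
                      ymin = .data$mean_lick_prob - .data$sd,
                      ymax = .data$mean_lick_prob + .data$sd),
                  inherit.aes = FALSE, alpha = 0.2) +
      geom_line(data = psychometric,
                aes(x = .data$location_mm, y = .data$mean_lick_prob),
                inherit.aes = FALSE, colour = "grey40")
  }
  p
}
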