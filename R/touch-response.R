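#' Peri-touch spike-time histogram
#'
#' Aligns spikes to touch onsets over a -50 to +50 ms support in 1-ms bins
#' and scales to spikes/s. Touches closer than `min_iti_ms` to a previous
#' touch onset are excluded from accumulation to avoid response overlap,
#' as are touches too close to trial edges to carry the full support.
#'
#' @param bundle a `session_bundle` with at least one touch.
#' @param support_ms half-width of the PSTH support (ms).
#' @param min_iti_ms minimum onset-to-onset interval (ms).
#' @return tibble with `time_ms` (-50..50) and `rate` (Hz); attributes
#'   `n_touches` and `per_touch_counts` (baseline and window counts per
#'   included touch, used for bootstrap CIs downstream).
#' @export
touch_psth <- function(bundle, support_ms = 50, min_iti_ms = 50) {
  stopifnot(inherits(bundle, "session_bundle"))
  to <- bundle$touches
  if (!nrow(to)) abort("touch_psth() requires at least one touch.")
  to <- arrange(to, .data$trial_id, .data$onset_ms)
  iti_ok <- unlist(lapply(split(to$onset_ms, to$trial_id), function(o) {
    c(TRUE, diff(o) >= min_iti_ms)
  }), use.names = FALSE)
  dur <- setNames(bundle$trials$duration_ms, bundle$trials$trial_id)
  edge_ok <- to$onset_ms >= support_ms &
    to$onset_ms + support_ms < dur[as.character(to$trial_id)]
  to <- to[iti_ok & edge_ok, ]
  if (!nrow(to)) abort("no touches with full PSTH support after exclusions.")
  sp <- split(bundle$spikes$time_ms, bundle$spikes$trial_id)
  bins <- seq(-support_ms, support_ms)
  counts <- numeric(length(bins))
  base_counts <- integer(nrow(to))
  for (i in seq_len(nrow(to))) {
    s <- sp[[as.character(to$trial_id[i])]]
    if (is.null(s)) next
    rel <- floor(s - to$onset_ms[i])
    rel <- rel[rel >= -support_ms & rel <= support_ms]
    if (length(rel)) {
      counts <- counts + tabulate(rel + support_ms + 1L, length(bins))
    }
    base_counts[i] <- sum(rel >= -support_ms & rel < 0)
  }
  out <- tibble(time_ms = bins, rate = counts / nrow(to) * 1000)
  attr(out, "n_touches") <- nrow(to)
  attr(out, "touches") <- to
  attr(out, "baseline_counts") <- base_counts
  out
}

#' Detect a neuron's touch-response window
#'
#' Smooths the peri-touch PSTH with an adaptive smoother
#' ([psth_segment_smoother()] by default; pass `smoother` to substitute
#' another) and finds the contiguous span within 5-50
#' ms post touch where the smoothed response exceeds the upper bound of
#' the baseline's 95% interval. Baseline is the mean rate over -50 to 0 ms
#' pre-touch; its 95% interval is the 2.5-97.5% band of the smoothed
#' baseline (so phase-locked pre-touch oscillation widens the band as it
#' should), floored at two standard errors of a minimal-window rate
#' estimate so that featureless baselines are not thresholded at their
#' own mean. A neuron is a touch unit only if the mean response in the
#' window exceeds 2 Hz and the window spans at least 4 ms (the shortest
#' response duration observed in real populations); if the
#' supra-threshold span is non-contiguous, the longest run is taken.
#'
#' @param bundle a `session_bundle`.
#' @param psth optional precomputed [touch_psth()].
#' @param window_bounds_ms candidate window limits post touch.
#' @param min_rate_hz,min_duration_ms the two touch-unit criteria.
#' @param smoother function(time_ms, rate) -> smoothed rate vector;
#'   default [psth_segment_smoother()] with the PSTH's touch count.
#' @return object of class `touch_profile`; see [glance.touch_profile()].
#' @export
detect_touch_window <- function(bundle, psth = NULL,
                                window_bounds_ms = c(5, 50),
                                min_rate_hz = 2, min_duration_ms = 4,
                                smoother = NULL) {
  if (is.null(psth)) psth <- touch_psth(bundle)
  n_touch <- attr(psth, "n_touches")
  if (is.null(smoother)) {
    smoother <- function(t, r) psth_segment_smoother(t, r, n_touch)
  }
  sm <- smoother(psth$time_ms, psth$rate)
  base_idx <- psth$time_ms >= -50 & psth$time_ms < 0
  baseline <- mean(psth$rate[base_idx])
  # counting noise of a rate estimated over the minimal (>4 ms) window
  se_min <- sqrt(max(baseline, 1) * 1000 / n_touch / (min_duration_ms + 1))
  ci <- unname(quantile(sm[base_idx], c(0.025, 0.975)))
  ci[2] <- max(ci[2], baseline + 1.96 * se_min)
  cand <- psth$time_ms >= window_bounds_ms[1] &
    psth$time_ms <= window_bounds_ms[2] & sm > ci[2]
  window <- NULL
  in_range <- which(psth$time_ms >= window_bounds_ms[1] &
                      psth$time_ms <= window_bounds_ms[2])
  runs <- runs_to_epochs(cand[in_range])
  if (nrow(runs)) {
    # trim run edges whose fitted segments are not individually elevated
    # above baseline (exact Poisson test on their pooled counts); guards
    # against chance boundary segments that sit marginally above the band
    counts <- psth$rate * n_touch / 1000
    trimmed <- lapply(seq_len(nrow(runs)), function(r) {
      trim_run_edges(in_range[runs$start[r]:runs$end[r]], sm, counts,
                     baseline * n_touch / 1000)
    })
    lens <- vapply(trimmed, length, integer(1))
    if (any(lens > 0)) {
      keep <- trimmed[[which.max(lens)]]
      window <- psth$time_ms[c(keep[1], keep[length(keep)])]
    }
  }
  mean_window_rate <- if (!is.null(window)) {
    idx <- psth$time_ms >= window[1] & psth$time_ms <= window[2]
    mean(psth$rate[idx])
  } else NA_real_
  duration <- if (!is.null(window)) window[2] - window[1] + 1 else NA_real_
  is_touch <- !is.null(window) && mean_window_rate > min_rate_hz &&
    duration >= min_duration_ms
  if (!is_touch) window <- NULL
  # per-touch spike counts / response probability within the final window
  spikes_per_touch <- NA_real_
  response_probability <- NA_real_
  if (!is.null(window)) {
    wc <- per_touch_window_counts(bundle, attr(psth, "touches"), window)
    spikes_per_touch <- mean(wc)
    response_probability <- mean(wc >= 1)
  }
  structure(
    list(
      psth = mutate(psth, smoothed = sm),
      n_touches = n_touch,
      baseline_mean = baseline, baseline_ci95 = ci,
      window = window,
      latency = if (!is.null(window)) window[1] else NA_real_,
      duration = if (!is.null(window)) duration else NA_real_,
      mean_window_rate = mean_window_rate,
      spikes_per_touch = spikes_per_touch,
      response_probability = response_probability,
      is_touch_unit = is_touch
    ),
    class = "touch_profile"
  )
}

#' Adaptive PSTH smoother: penalised Poisson segmentation
#'
#' Piecewise-constant fit of pooled per-bin spike counts by optimal
#' partitioning (dynamic programming) under a Poisson likelihood with a
#' BIC-type penalty per changepoint. Like adaptive regression splines,
#' the fit is flat wherever the data are flat and follows sharp
#' transitions exactly, which is what peri-touch histograms of
#' short-latency responses require; a fixed-bandwidth smoother cannot do
#' both. Returns the fitted rate in Hz on the PSTH support.
#'
#' @param time_ms PSTH bin times.
#' @param rate per-bin rate in Hz (averaged over `n_touches`).
#' @param n_touches touches pooled into the PSTH.
#' @param penalty penalty per changepoint; default `2 * log(n)` (two
#'   parameters per added segment).
#' @return smoothed rate vector (Hz).
#' @export
psth_segment_smoother <- function(time_ms, rate, n_touches,
                                  penalty = NULL) {
  y <- round(rate * n_touches / 1000)
  n <- length(y)
  if (is.null(penalty)) penalty <- 2 * log(n)
  cs <- c(0, cumsum(y))
  # -2 x Poisson log-likelihood of segment i..j, up to a data-only constant
  fcost <- c(0, rep(Inf, n))
  cp <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    nseg <- j - i + 1
    sseg <- cs[j + 1] - cs[i]
    cost <- ifelse(sseg == 0, 0,
                   -2 * (sseg * log(sseg / nseg) - sseg))
    v <- fcost[i] + cost + penalty
    arg <- which.min(v)
    fcost[j + 1] <- v[arg]
    cp[j] <- arg - 1L
  }
  fit <- numeric(n)
  j <- n
  while (j > 0) {
    i <- cp[j] + 1L
    fit[i:j] <- (cs[j + 1] - cs[i]) / (j - i + 1)
    j <- i - 1L
  }
  fit / n_touches * 1000
}

# Drop leading/trailing fitted segments of a supra-threshold run whose
# pooled spike counts are not significantly above the baseline expectation
# (one-sided exact Poisson test at `alpha` per edge segment). `idx` are
# absolute PSTH indices; returns the surviving index span (possibly empty).
trim_run_edges <- function(idx, sm, counts, base_per_bin, alpha = 0.001) {
  segs <- rle(sm[idx])
  ends <- cumsum(segs$lengths)
  starts <- ends - segs$lengths + 1L
  sig <- vapply(seq_along(starts), function(s) {
    obs <- sum(counts[idx[starts[s]:ends[s]]])
    expct <- base_per_bin * segs$lengths[s]
    stats::ppois(obs - 1, expct, lower.tail = FALSE) < alpha
  }, logical(1))
  lo <- 1L
  hi <- length(sig)
  while (lo <= hi && !sig[lo]) lo <- lo + 1L
  while (hi >= lo && !sig[hi]) hi <- hi - 1L
  if (lo > hi) return(integer(0))
  idx[starts[lo]:ends[hi]]
}

# Spike counts per touch inside [onset + window] (window in ms post touch).
per_touch_window_counts <- function(bundle, touches, window) {
  sp <- split(bundle$spikes$time_ms, bundle$spikes$trial_id)
  vapply(seq_len(nrow(touches)), function(i) {
    s <- sp[[as.character(touches$trial_id[i])]]
    if (is.null(s)) return(0)
    o <- touches$onset_ms[i]
    sum(s >= o + window[1] & s < o + window[2] + 1)
  }, numeric(1))
}

#' @exportS3Method base::print
print.touch_profile <- function(x, ...) {
  if (x$is_touch_unit) {
    cat(sprintf(
      "<touch_profile: touch unit; window %g-%g ms, %.1f Hz in window, baseline %.2f Hz, %d touches>\n",
      x$window[1], x$window[2], x$mean_window_rate, x$baseline_mean,
      x$n_touches))
  } else {
    cat(sprintf("<touch_profile: not a touch unit (baseline %.2f Hz, %d touches)>\n",
                x$baseline_mean, x$n_touches))
  }
  invisible(x)
}

#' Session summary metrics for one neuron
#'
#' Computes the standard per-neuron characterisation: whisking and quiet
#' firing rates, proportion of spikes inside touch-response windows,
#' proportion inside touch windows or whisking epochs, mean spikes per
#' touch in the response window, and per-touch response probability.
#' Non-touch units use the population fallback window (10-28 ms post
#' touch, the median touch-response window).
#'
#' @param bundle a `session_bundle`.
#' @param profile a [detect_touch_window()] result.
#' @param kin optional precomputed [session_kinematics()].
#' @param fallback_window fallback response window (ms post touch).
#' @return one-row tibble of summary metrics; touch metrics are `NA` when
#'   the session has no touches.
#' @export
touch_summary <- function(bundle, profile, kin = NULL,
                          fallback_window = c(10, 28)) {
  stopifnot(inherits(profile, "touch_profile"))
  wr <- whisking_rate_comparison(bundle, kin = kin)
  window <- profile$window %||% fallback_window
  n_spikes <- nrow(bundle$spikes)
  if (nrow(bundle$touches)) {
    to <- arrange(bundle$touches, .data$trial_id, .data$onset_ms)
    wc <- per_touch_window_counts(bundle, to, window)
    in_touch <- spikes_in_windows(bundle, to, window)
    prop_touch <- if (n_spikes) sum(in_touch) / n_spikes else 0
    spikes_per_touch <- mean(wc)
    resp_prob <- mean(wc >= 1)
  } else {
    prop_touch <- NA_real_
    spikes_per_touch <- NA_real_
    resp_prob <- NA_real_
    in_touch <- logical(n_spikes)
  }
  in_whisk <- spikes_in_whisking(bundle, kin)
  prop_touch_or_whisk <- if (n_spikes) {
    sum(in_touch | in_whisk) / n_spikes
  } else 0
  tibble(
    rate_whisking = wr$rate_whisking, rate_quiet = wr$rate_quiet,
    whisking_modulated = wr$modulated,
    prop_spikes_touch = prop_touch,
    prop_spikes_touch_or_whisking = prop_touch_or_whisk,
    spikes_per_touch = spikes_per_touch,
    response_probability = resp_prob,
    is_touch_unit = profile$is_touch_unit,
    latency_ms = profile$latency, duration_ms = profile$duration
  )
}

spikes_in_windows <- function(bundle, touches, window) {
  sp <- bundle$spikes
  flag <- logical(nrow(sp))
  for (tid in unique(touches$trial_id)) {
    rows <- which(sp$trial_id == tid)
    if (!length(rows)) next
    o <- touches$onset_ms[touches$trial_id == tid]
    for (oo in o) {
      flag[rows] <- flag[rows] |
        (sp$time_ms[rows] >= oo + window[1] &
           sp$time_ms[rows] < oo + window[2] + 1)
    }
  }
  flag
}

spikes_in_whisking <- function(bundle, kin = NULL) {
  if (is.null(kin)) kin <- session_kinematics(bundle)
  state <- split(kin$whisking, kin$trial_id)
  sp <- bundle$spikes
  flag <- logical(nrow(sp))
  for (tid in names(state)) {
    rows <- which(sp$trial_id == as.integer(tid))
    if (!length(rows)) next
    idx <- pmin(pmax(floor(sp$time_ms[rows]) + 1L, 1L), length(state[[tid]]))
    flag[rows] <- state[[tid]][idx]
  }
  flag
}
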