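#' Build an equal-occupancy tuning curve
#'
#' Sorts samples by stimulus value (stable sort, so ties at bin boundaries
#' are broken by input order), partitions them into `n_bins` bins of equal
#' occupancy (5% of samples per bin at the default 20), and summarises
#' each bin by its median stimulus and mean response. The curve is
#' smoothed with a penalised cubic smoothing spline (GCV), evaluated at
#' the bin medians; pass `smoother` to substitute another smoother.
#'
#' @param data tibble of per-sample records (one row per touch or per
#'   whisking time point).
#' @param stimulus,response unquoted column names: stimulus value and
#'   response (rate in Hz, or spike count).
#' @param n_bins number of equal-occupancy bins (default 20).
#' @param stimulus_name label stored on the curve.
#' @param smoother function(x, y) -> fitted values at x.
#' @return object of class `tuning_curve`: a tibble with `bin`,
#'   `stimulus` (bin median), `response` (bin mean), `occupancy`,
#'   `smoothed`; the per-sample records with bin assignment are kept in
#'   attribute `samples` for the significance and width tests.
#' @examples
#' d <- tibble::tibble(x = runif(400, 0, 10),
#'                     y = rpois(400, 2 * exp(-(runif(400, 0, 10) - 5)^2 / 2)))
#' build_tuning_curve(d, x, y)
#' @export
build_tuning_curve <- function(data, stimulus, response, n_bins = 20,
                               stimulus_name = NULL, smoother = NULL) {
  s <- dplyr::pull(data, {{ stimulus }})
  r <- dplyr::pull(data, {{ response }})
  if (is.null(stimulus_name)) stimulus_name <- as_name(enquo(stimulus))
  ok <- is.finite(s) & is.finite(r)
  s <- s[ok]; r <- r[ok]
  n <- length(s)
  if (n < 2L * n_bins) {
    abort(sprintf(
      "need at least %d samples for %d equal-occupancy bins (got %d).",
      2L * n_bins, n_bins, n))
  }
  ord <- order(s)  # stable
  bin <- integer(n)
  bin[ord] <- equal_occupancy_bins(n, n_bins)
  samples <- tibble(stimulus = s, response = r, bin = bin)
  curve <- samples |>
    group_by(.data$bin) |>
    summarise(stimulus = median(.data$stimulus),
              response = mean(.data$response),
              occupancy = dplyr::n(), .groups = "drop") |>
    arrange(.data$bin)
  if (is.null(smoother)) smoother <- curve_smoother
  curve$smoothed <- smoother(curve$stimulus, curve$response)
  out <- structure(curve, class = c("tuning_curve", class(curve)))
  attr(out, "samples") <- samples
  attr(out, "stimulus_name") <- stimulus_name
  out
}

curve_smoother <- function(x, y) {
  if (stats::var(y) == 0) return(y)
  # df capped below n to keep the stand-in spline from interpolating noise
  fit <- tryCatch(smooth.spline(x, y, cv = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) return(y)
  as.numeric(predict(fit, x)$y)
}

#' Two-step significance test for a tuning curve
#'
#' Step 1: one-way ANOVA of responses across the equal-occupancy bins at
#' `alpha` (default 0.01). Step 2: permute the response labels
#' `n_shuffles` times (default 1,000), recompute the F statistic each
#' time, and require the observed F to exceed the 95th percentile of the
#' shuffled F distribution. The curve is tuned only if both steps pass.
#'
#' @param tc a `tuning_curve`.
#' @param n_shuffles permutations.
#' @param alpha ANOVA significance level.
#' @param shuffle_quantile percentile of the shuffled F distribution.
#' @param seed permutation seed.
#' @return `tc` with fields `is_tuned`, `F_observed`, `p_anova`,
#'   `F_shuffle_95` set (retrievable via [glance.tuning_curve()]).
#' @export
test_tuning <- function(tc, n_shuffles = 1000, alpha = 0.01,
                        shuffle_quantile = 0.95, seed = 1) {
  stopifnot(inherits(tc, "tuning_curve"))
  sm <- attr(tc, "samples")
  f_obs <- oneway_f(sm$response, sm$bin)
  if (!is.finite(f_obs)) {
    attr(tc, "test") <- list(is_tuned = FALSE, F_observed = NA_real_,
                             p_anova = NA_real_, F_shuffle_95 = NA_real_)
    return(tc)
  }
  k <- length(unique(sm$bin))
  n <- nrow(sm)
  p <- pf(f_obs, k - 1, n - k, lower.tail = FALSE)
  f_shuf <- withr::with_seed(seed, {
    # chunked so the permutation matrix stays within ~2e7 entries
    chunk <- max(1L, min(n_shuffles, floor(2e7 / n)))
    starts <- seq(1L, n_shuffles, by = chunk)
    unlist(lapply(starts, function(s) {
      m <- min(chunk, n_shuffles - s + 1L)
      perm <- replicate(m, sample.int(n))
      oneway_f(matrix(sm$response[perm], nrow = n), sm$bin)
    }))
  })
  f95 <- unname(quantile(f_shuf, shuffle_quantile, na.rm = TRUE))
  attr(tc, "test") <- list(
    is_tuned = p < alpha && f_obs > f95,
    F_observed = unname(f_obs), p_anova = p, F_shuffle_95 = f95
  )
  tc
}

#' Tuning width from multiple comparisons and from the smoothed curve
#'
#' Identifies the first bins on each side of the peak whose responses
#' differ significantly from the peak bin under a Tukey-Kramer-type
#' critical value (studentised range over the bin family at
#' `conf.level`), and reports the full width at half maximum (FWHM) of
#' the smoothed curve around its peak for normalised-shape comparisons.
#'
#' @param tc a tested `tuning_curve` (run [test_tuning()] first; untuned
#'   curves return `NA` widths).
#' @param conf.level family confidence level for the Tukey-Kramer test.
#' @return `tc` with a `width` attribute: `width_bins` (indices of first
#'   significantly different bins below/above the peak, or `NA`),
#'   `half_max_width` in stimulus units, and `peak_bin`/`preference`.
#' @export
tuning_width <- function(tc, conf.level = 0.95) {
  stopifnot(inherits(tc, "tuning_curve"))
  test <- attr(tc, "test")
  peak_bin <- which.max(tc$smoothed)
  preference <- tc$stimulus[peak_bin]
  out <- list(peak_bin = peak_bin, preference = preference,
              width_bins = c(NA_integer_, NA_integer_),
              half_max_width = NA_real_)
  if (is.null(test) || !isTRUE(test$is_tuned)) {
    attr(tc, "width") <- out
    return(tc)
  }
  sm <- attr(tc, "samples")
  k <- length(unique(sm$bin))
  n <- nrow(sm)
  ng <- tabulate(sm$bin)
  means <- tapply(sm$response, sm$bin, mean)
  mse <- sum(tapply(sm$response, sm$bin,
                    function(v) sum((v - mean(v))^2))) / (n - k)
  qcrit <- qtukey(conf.level, nmeans = k, df = n - k)
  # raw-response peak bin for the comparison family
  rpeak <- which.max(means)
  sig <- vapply(seq_len(k), function(j) {
    if (j == rpeak) return(FALSE)
    se <- sqrt(mse / 2 * (1 / ng[j] + 1 / ng[rpeak]))
    abs(means[j] - means[rpeak]) / se > qcrit
  }, logical(1))
  below <- which(sig & seq_len(k) < rpeak)
  above <- which(sig & seq_len(k) > rpeak)
  out$width_bins <- c(
    if (length(below)) max(below) else NA_integer_,
    if (length(above)) min(above) else NA_integer_
  )
  out$half_max_width <- fwhm(tc$stimulus, tc$smoothed)
  attr(tc, "width") <- out
  tc
}

# Full width at half maximum of a curve around its global peak, by linear
# interpolation on a dense grid.
fwhm <- function(x, y) {
  if (length(x) < 3 || max(y) == min(y)) return(NA_real_)
  grid <- seq(min(x), max(x), length.out = 512)
  yg <- approx(x, y, xout = grid)$y
  half <- min(yg) + (max(yg) - min(yg)) / 2
  ipk <- which.max(yg)
  lo <- grid[1]
  if (ipk > 1) {
    for (i in rev(seq_len(ipk - 1))) {
      if (yg[i] < half) {
        lo <- grid[i] + (grid[i + 1] - grid[i]) * (half - yg[i]) /
          (yg[i + 1] - yg[i])
        break
      }
    }
  }
  hi <- grid[length(grid)]
  if (ipk < length(grid)) {
    for (i in (ipk + 1):length(grid)) {
      if (yg[i] < half) {
        hi <- grid[i - 1] + (grid[i] - grid[i - 1]) * (yg[i - 1] - half) /
          (yg[i - 1] - yg[i])
        break
      }
    }
  }
  hi - lo
}

#' Modulation depths of a tuning curve
#'
#' Absolute modulation depth is `max - min` of the smoothed curve;
#' normalised modulation depth is `(max - min) / (max + min)`. Both use
#' the smoothed curve evaluated at the 20 bin medians.
#'
#' @param tc a `tuning_curve`.
#' @return one-row tibble `abs_mod_depth`, `mod_depth` (`NA` and flagged
#'   when `max + min` is 0).
#' @export
modulation_depths <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve"))
  mx <- max(tc$smoothed)
  mn <- min(tc$smoothed)
  tibble(
    abs_mod_depth = mx - mn,
    mod_depth = if ((mx + mn) == 0) NA_real_ else (mx - mn) / (mx + mn),
    undefined = (mx + mn) == 0
  )
}

#' Stratify a tuning curve by a covariate (median split per bin)
#'
#' Within each equal-occupancy stimulus bin, samples are split at the
#' bin's covariate median into high and low halves and a curve is built
#' for each half; used to control object-location tuning for touch
#' strength (max curvature change). Bins with fewer than `min_per_bin`
#' samples are excluded from the split.
#'
#' @param data per-sample tibble.
#' @param stimulus,response,covariate unquoted column names.
#' @param n_bins bins.
#' @param min_per_bin minimum samples per bin to split.
#' @return list with `high` and `low` per-bin curves (tibbles `bin`,
#'   `stimulus`, `response`, `n`), and `rate_increase`: the mean
#'   fractional elevation of the high half over the low half.
#' @export
stratified_tuning <- function(data, stimulus, response, covariate,
                              n_bins = 20, min_per_bin = 4) {
  s <- dplyr::pull(data, {{ stimulus }})
  r <- dplyr::pull(data, {{ response }})
  cv <- dplyr::pull(data, {{ covariate }})
  if (stats::var(cv) == 0) abort("covariate is constant; split undefined.")
  n <- length(s)
  if (n < 2L * n_bins) abort("too few samples to stratify.")
  ord <- order(s)
  bin <- integer(n)
  bin[ord] <- equal_occupancy_bins(n, n_bins)
  d <- tibble(stimulus = s, response = r, covariate = cv, bin = bin)
  halves <- d |>
    group_by(.data$bin) |>
    filter(dplyr::n() >= min_per_bin) |>
    mutate(high = .data$covariate > median(.data$covariate)) |>
    group_by(.data$bin, .data$high) |>
    summarise(stimulus = median(.data$stimulus),
              response = mean(.data$response), n = dplyr::n(),
              .groups = "drop")
  high <- filter(halves, .data$high) |> select(-"high")
  low <- filter(halves, !.data$high) |> select(-"high")
  joint <- dplyr::inner_join(high, low, by = "bin",
                             suffix = c("_high", "_low"))
  ok <- joint$response_low > 0
  rate_increase <- if (any(ok)) {
    mean(joint$response_high[ok] / joint$response_low[ok] - 1)
  } else NA_real_
  list(high = high, low = low, rate_increase = rate_increase)
}

#' Per-bin Fano factors of touch-evoked spike counts
#'
#' Bins samples as in [build_tuning_curve()] and reports the
#' variance-to-mean ratio of the (integer) counts per bin; zero-mean bins
#' are skipped.
#'
#' @param data per-sample tibble.
#' @param stimulus,count unquoted columns (count = spikes per touch).
#' @param n_bins bins.
#' @return tibble `bin`, `stimulus`, `mean_count`, `fano`, plus attribute
#'   `summary` = c(mean, sd) over bins.
#' @export
fano_per_bin <- function(data, stimulus, count, n_bins = 20) {
  s <- dplyr::pull(data, {{ stimulus }})
  k <- dplyr::pull(data, {{ count }})
  n <- length(s)
  if (n < 2L * n_bins) abort("too few samples for Fano binning.")
  ord <- order(s)
  bin <- integer(n)
  bin[ord] <- equal_occupancy_bins(n, n_bins)
  out <- tibble(stimulus = s, count = k, bin = bin) |>
    group_by(.data$bin) |>
    summarise(stimulus = median(.data$stimulus),
              mean_count = mean(.data$count),
              fano = if (mean(.data$count) > 0) {
                var(.data$count) / mean(.data$count)
              } else NA_real_,
              .groups = "drop")
  attr(out, "summary") <- c(mean = mean(out$fano, na.rm = TRUE),
                            sd = sd(out$fano, na.rm = TRUE))
  out
}

#' Per-touch tuning samples for a session
#'
#' Extracts one row per touch with the stimulus value (pole location or
#' whisker angle at touch), the spike count in the neuron's
#' touch-response window, and the equivalent rate in Hz. Non-touch units
#' use the fallback 10-28 ms window (the population median).
#'
#' @param bundle a `session_bundle`.
#' @param profile a [detect_touch_window()] result (or `NULL` to force
#'   the fallback window).
#' @param fallback_window ms post touch.
#' @return tibble `trial_id`, `pole_location_mm`, `angle_at_touch`,
#'   `max_curvature_change`, `count`, `rate_hz`, `window_ms`.
#' @export
touch_tuning_data <- function(bundle, profile = NULL,
                              fallback_window = c(10, 28)) {
  window <- if (!is.null(profile) && profile$is_touch_unit) {
    profile$window
  } else fallback_window
  to <- arrange(bundle$touches, .data$trial_id, .data$onset_ms)
  if (!nrow(to)) abort("session has no touches.")
  wc <- per_touch_window_counts(bundle, to, window)
  wlen <- window[2] - window[1] + 1
  loc <- setNames(bundle$trials$pole_location_mm, bundle$trials$trial_id)
  tibble(
    trial_id = to$trial_id,
    pole_location_mm = unname(loc[as.character(to$trial_id)]),
    angle_at_touch = to$angle_at_touch,
    max_curvature_change = to$max_curvature_change,
    count = wc,
    rate_hz = wc / wlen * 1000,
    window_ms = wlen
  )
}

#' Per-time-point whisking tuning samples
#'
#' For each whisking (amplitude > 5 degrees) millisecond, records the
#' kinematic stimulus values and the firing rate in the touch-response
#' window offset from that time point (the same integration window as the
#' touch analysis; non-touch units use the 10-28 ms fallback).
#'
#' @param bundle a `session_bundle`.
#' @param profile a [detect_touch_window()] result or `NULL`.
#' @param kin optional precomputed [session_kinematics()].
#' @param fallback_window ms.
#' @param min_rate_hz curves are only evaluated when the mean whisking
#'   response reaches this rate (default 2 Hz); below it `NULL` is
#'   returned with a message.
#' @return tibble `trial_id`, `time_ms`, `angle`, `phase`, `amplitude`,
#'   `midpoint`, `velocity`, `count`, `rate_hz`, or `NULL`.
#' @export
whisking_tuning_data <- function(bundle, profile = NULL, kin = NULL,
                                 fallback_window = c(10, 28),
                                 min_rate_hz = 2) {
  window <- if (!is.null(profile) && profile$is_touch_unit) {
    profile$window
  } else fallback_window
  if (is.null(kin)) kin <- session_kinematics(bundle)
  kin <- kin[!kin$masked & kin$whisking, ]
  if (!nrow(kin)) return(NULL)
  sp <- split(bundle$spikes$time_ms, bundle$spikes$trial_id)
  wlen <- window[2] - window[1] + 1
  dur <- setNames(bundle$trials$duration_ms, bundle$trials$trial_id)
  counts <- integer(nrow(kin))
  offset <- 0L
  for (tid in unique(kin$trial_id)) {
    rows <- which(kin$trial_id == tid)
    t0 <- kin$time_ms[rows]
    cum <- numeric(dur[as.character(tid)] + 1L)
    s <- sp[[as.character(tid)]]
    if (!is.null(s)) {
      tb <- tabulate(floor(s) + 1L, nbins = dur[as.character(tid)])
      cum <- c(0, cumsum(tb))
    }
    a <- pmin(t0 + window[1], length(cum) - 1L)
    b <- pmin(t0 + window[2] + 1L, length(cum) - 1L)
    counts[rows] <- cum[b + 1L] - cum[a + 1L]
  }
  out <- tibble(
    trial_id = kin$trial_id, time_ms = kin$time_ms,
    angle = kin$angle, phase = kin$phase, amplitude = kin$amplitude,
    midpoint = kin$midpoint, velocity = kin$velocity,
    count = counts, rate_hz = counts / wlen * 1000
  )
  if (mean(out$rate_hz) < min_rate_hz) {
    inform(sprintf(
      "mean whisking response %.2f Hz < %g Hz; whisking tuning not evaluated.",
      mean(out$rate_hz), min_rate_hz))
    return(NULL)
  }
  out
}
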