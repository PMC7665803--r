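#' Decompose a whisker-angle trace into amplitude, midpoint and phase
#'
#' Band-passes the 1-kHz whisker-angle series to the whisking band
#' (6-60 Hz, 4th-order Butterworth, applied forward-backward for zero
#' phase), then takes the analytic signal of the band-passed trace.
#' Instantaneous amplitude is the magnitude and phase the angle of the
#' analytic signal; phase 0 is the most protracted point of the whisk
#' cycle and +/-pi the most retracted. The midpoint (slow set-point) is the
#' residual `angle - bandpassed`, low-pass filtered below the whisking band.
#' Velocity is the centred first difference in degrees/s.
#'
#' @param angle numeric vector, whisker azimuthal angle in degrees sampled
#'   at `fs` Hz. At least 256 samples (filter warm-up).
#' @param fs sampling rate in Hz (recordings are tracked at 1,000
#'   frames/s, so the default is 1000).
#' @param band two-element numeric, pass band in Hz.
#' @param order Butterworth order.
#' @param amp_threshold degrees; amplitude above this marks whisking (see
#'   [segment_whisking()]).
#' @param ... passed to [segment_whisking()] (bout hygiene parameters).
#' @return A `kinematic_series`: a tibble with columns `time_ms`, `angle`,
#'   `bandpassed`, `amplitude`, `midpoint`, `phase`, `velocity`,
#'   `whisking`. Phase is only meaningful where `whisking` is `TRUE`
#'   (amplitude above threshold); it is stored everywhere but flagged by
#'   the `whisking` column.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' ks <- hilbert_decompose(70 + 15 * cos(2 * pi * 12 * t))
#' summary(ks$amplitude[200:1800])
#' @export
hilbert_decompose <- function(angle, fs = 1000, band = c(6, 60), order = 4,
                              amp_threshold = 5, ...) {
  if (length(angle) < 256L) {
    abort("`angle` must have at least 256 samples for stable filtering.")
  }
  if (!all(is.finite(angle))) abort("`angle` must be finite.")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # remove the DC offset first: a large offset leaks filter edge transients
  bp <- as.numeric(signal::filtfilt(bf, angle - mean(angle)))
  z <- analytic_signal(bp)
  lf <- signal::butter(2, band[1] / (fs / 2), type = "low")
  mid <- as.numeric(signal::filtfilt(lf, angle - bp))
  n <- length(angle)
  vel <- c(
    (angle[2L] - angle[1L]) * fs,
    (angle[3:n] - angle[1:(n - 2L)]) / 2 * fs,
    (angle[n] - angle[n - 1L]) * fs
  )
  ks <- tibble(
    time_ms = (seq_len(n) - 1L) * (1000 / fs),
    angle = angle,
    bandpassed = bp,
    amplitude = Mod(z),
    midpoint = mid,
    phase = Arg(z),
    velocity = vel,
    whisking = FALSE
  )
  class(ks) <- c("kinematic_series", class(ks))
  segment_whisking(ks, amp_threshold = amp_threshold, ...)
}

#' Segment whisking versus quiet periods by amplitude threshold
#'
#' Whisking is where instantaneous amplitude exceeds `amp_threshold`
#' (default 5 degrees, the threshold used to mask phase). Gaps shorter than
#' `merge_gap_ms` between whisking runs are bridged and runs shorter than
#' `min_bout_ms` dropped, to remove chatter at the threshold boundary.
#'
#' @param ks a `kinematic_series` from [hilbert_decompose()].
#' @param amp_threshold degrees.
#' @param merge_gap_ms,min_bout_ms bout hygiene in ms.
#' @return `ks` with its `whisking` column recomputed.
#' @export
segment_whisking <- function(ks, amp_threshold = 5, merge_gap_ms = 50,
                             min_bout_ms = 50) {
  stopifnot(inherits(ks, "kinematic_series"))
  raw <- ks$amplitude > amp_threshold
  ks$whisking <- tidy_runs(raw, merge_gap = merge_gap_ms, min_run = min_bout_ms)
  ks
}

#' Whisking epochs as start/end times
#'
#' @param ks a `kinematic_series`.
#' @return tibble with `start_ms`, `end_ms` (inclusive) per whisking bout.
#' @export
whisking_epochs <- function(ks) {
  ep <- runs_to_epochs(ks$whisking)
  tibble(start_ms = ks$time_ms[ep$start], end_ms = ks$time_ms[ep$end])
}

#' Kinematic decomposition for every tracked trial of a session
#'
#' Runs [hilbert_decompose()] on each trial's whisker trace. Trials with
#' masked (untracked) samples exclude those samples from downstream state
#' assignment; trials with no tracked samples are skipped.
#'
#' @param bundle a `session_bundle`.
#' @param ... passed to [hilbert_decompose()].
#' @return tibble with `trial_id` plus all `kinematic_series` columns and a
#'   `masked` flag.
#' @export
session_kinematics <- function(bundle, ...) {
  stopifnot(inherits(bundle, "session_bundle"))
  w <- bundle$whisker
  per_trial <- lapply(split(w, w$trial_id), function(tr) {
    if (all(tr$masked)) return(NULL)
    ks <- hilbert_decompose(tr$angle, fs = bundle$meta$sampling_rate, ...)
    ks$trial_id <- tr$trial_id[1L]
    ks$masked <- tr$masked
    ks
  })
  out <- bind_rows(per_trial)
  select(out, "trial_id", dplyr::everything())
}

#' Compare firing rates between whisking and quiet states
#'
#' Pools whisking and quiet (non-whisking) time across a session's tracked
#' trials, computes the firing rate in each state, and tests whether
#' spiking is modulated by whisking with a 1-df chi-squared goodness-of-fit
#' test of the observed spike counts against expectation proportional to
#' time spent in each state.
#'
#' @param bundle a `session_bundle`.
#' @param kin optional precomputed [session_kinematics()] output.
#' @param alpha significance level for the modulation call (default 0.01).
#' @param min_state_s minimum time (s) in each state for the test to be
#'   defined.
#' @param ... passed to [session_kinematics()].
#' @return one-row tibble: `rate_whisking`, `rate_quiet` (Hz),
#'   `time_whisking_s`, `time_quiet_s`, `n_spikes_whisking`,
#'   `n_spikes_quiet`, `chisq`, `p_value`, `modulated`, `defined`.
#' @export
whisking_rate_comparison <- function(bundle, kin = NULL, alpha = 0.01,
                                     min_state_s = 1, ...) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (is.null(kin)) kin <- session_kinematics(bundle, ...)
  kin <- kin[!kin$masked, ]
  state <- split(kin$whisking, kin$trial_id)
  sp <- bundle$spikes
  in_whisk <- logical(nrow(sp))
  for (tid in names(state)) {
    rows <- which(sp$trial_id == as.integer(tid))
    if (!length(rows)) next
    idx <- pmin(pmax(floor(sp$time_ms[rows]) + 1L, 1L), length(state[[tid]]))
    in_whisk[rows] <- state[[tid]][idx]
  }
  tracked_trials <- as.integer(names(state))
  counted <- sp$trial_id %in% tracked_trials
  n_w <- sum(in_whisk & counted)
  n_q <- sum(!in_whisk & counted)
  t_w <- sum(kin$whisking) / 1000
  t_q <- sum(!kin$whisking) / 1000
  rate_w <- if (t_w > 0) n_w / t_w else 0
  rate_q <- if (t_q > 0) n_q / t_q else 0
  defined <- t_w >= min_state_s && t_q >= min_state_s
  if (defined && (n_w + n_q) > 0) {
    ct <- suppressWarnings(
      chisq.test(c(n_w, n_q), p = c(t_w, t_q) / (t_w + t_q))
    )
    chisq <- unname(ct$statistic)
    p <- unname(ct$p.value)
  } else {
    chisq <- NA_real_
    p <- NA_real_
  }
  tibble(
    rate_whisking = rate_w, rate_quiet = rate_q,
    time_whisking_s = t_w, time_quiet_s = t_q,
    n_spikes_whisking = n_w, n_spikes_quiet = n_q,
    chisq = chisq, p_value = p,
    modulated = isTRUE(!is.na(p) && p < alpha),
    defined = defined
  )
}
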