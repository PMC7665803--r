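#' Whisking generator parameters
#'
#' Describes the rhythmic whisking process used by the synthetic-session
#' generator: bouts arrive as a renewal process, each bout carries a
#' constant-frequency oscillation (carrier inside the 6-60 Hz analysis
#' band) under a raised-cosine amplitude envelope, riding on a slow
#' (< 6 Hz) midpoint drift around a quiet set-point.
#'
#' @param bout_rate bouts per second of non-bout time.
#' @param bout_duration_s mean bout duration (s); durations are log-normal
#'   with 30% dispersion.
#' @param carrier_freq_hz carrier frequency, must lie in `[6, 60]`.
#' @param freq_jitter fractional per-bout jitter of the carrier.
#' @param amplitude_range degrees, min and max per-bout amplitude.
#' @param midpoint_drift_sd degrees, SD of the slow midpoint drift.
#' @param quiet_angle degrees, resting whisker angle.
#' @return list of class `whisking_model`.
#' @export
whisking_model <- function(bout_rate = 1, bout_duration_s = 0.7,
                           carrier_freq_hz = 16, freq_jitter = 0.15,
                           amplitude_range = c(12, 28),
                           midpoint_drift_sd = 2.5, quiet_angle = 70) {
  if (carrier_freq_hz < 6 || carrier_freq_hz > 60) {
    abort("`carrier_freq_hz` must lie in the 6-60 Hz analysis band.")
  }
  amplitude_range <- rep_len(amplitude_range, 2L)
  structure(
    list(bout_rate = bout_rate, bout_duration_s = bout_duration_s,
         carrier_freq_hz = carrier_freq_hz, freq_jitter = freq_jitter,
         amplitude_range = amplitude_range,
         midpoint_drift_sd = midpoint_drift_sd, quiet_angle = quiet_angle),
    class = "whisking_model"
  )
}

#' Ground-truth neuron parameters for the session generator
#'
#' Parameterises baseline firing, whisking modulation (multiplicative gain
#' plus optional Gaussian angle tuning and cosine phase tuning), and
#' touch-evoked responses (latency, window, Gaussian object-location
#' tuning of the expected spike count per touch, with controllable count
#' dispersion). Defaults follow the population medians for touch latency
#' (10 ms), response duration (17 ms), spikes per touch (~0.7) and
#' near-Poisson dispersion (Fano 0.94).
#'
#' @param baseline_rate Hz.
#' @param whisking_gain multiplicative rate factor during whisking.
#' @param angle_pref,angle_kappa degrees; Gaussian free-whisking angle
#'   tuning (`NULL` angle_pref disables).
#' @param phase_pref,phase_depth radians and `[0,1]`; cosine phase tuning
#'   (`NULL` phase_pref disables).
#' @param touch_responsive logical.
#' @param touch_latency_ms,touch_window_ms response onset and duration.
#' @param location_pref,location_sd mm; Gaussian location tuning of the
#'   per-touch spike count (`NULL` location_pref gives untuned touch
#'   responses).
#' @param peak_touch_spikes expected spike count per touch at preference.
#' @param count_dispersion target Fano factor of per-touch counts.
#' @return list of class `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(baseline_rate = 3, whisking_gain = 1,
                                angle_pref = NULL, angle_kappa = 8,
                                phase_pref = NULL, phase_depth = 0.5,
                                touch_responsive = TRUE,
                                touch_latency_ms = 10, touch_window_ms = 17,
                                location_pref = 5, location_sd = 1,
                                peak_touch_spikes = 0.7,
                                count_dispersion = 0.94) {
  stopifnot(baseline_rate >= 0, peak_touch_spikes >= 0, count_dispersion > 0)
  if (!is.null(location_pref) &&
      (location_pref < 0 || location_pref > 10)) {
    abort("`location_pref` must lie in [0, 10] mm when set.")
  }
  structure(
    list(baseline_rate = baseline_rate, whisking_gain = whisking_gain,
         angle_pref = angle_pref, angle_kappa = angle_kappa,
         phase_pref = phase_pref, phase_depth = phase_depth,
         touch_responsive = touch_responsive,
         touch_latency_ms = touch_latency_ms,
         touch_window_ms = touch_window_ms,
         location_pref = location_pref, location_sd = location_sd,
         peak_touch_spikes = peak_touch_spikes,
         count_dispersion = count_dispersion),
    class = "ground_truth_neuron"
  )
}

#' Expected touch-evoked spike count at a pole location
#'
#' The generating tuning function: a Gaussian bump over anteroposterior
#' pole location, peaking at `location_pref` with width `location_sd`,
#' scaled to `peak_touch_spikes`; constant when the neuron has no location
#' preference, and 0 when it is not touch responsive.
#'
#' @param neuron a `ground_truth_neuron`.
#' @param x pole locations (mm).
#' @return expected counts, same length as `x`.
#' @export
true_touch_lambda <- function(neuron, x) {
  if (!neuron$touch_responsive) return(rep(0, length(x)))
  if (is.null(neuron$location_pref)) {
    return(rep(neuron$peak_touch_spikes, length(x)))
  }
  neuron$peak_touch_spikes *
    exp(-(x - neuron$location_pref)^2 / (2 * neuron$location_sd^2))
}

# Core whisking synthesis on the current RNG stream.
sim_whisking_core <- function(model, n_ms) {
  t_s <- (seq_len(n_ms) - 1L) / 1000
  envelope <- numeric(n_ms)
  phase <- numeric(n_ms)
  # renewal bout schedule
  t <- 0
  bouts <- list()
  while (t < n_ms / 1000) {
    onset <- t + stats::rexp(1, rate = max(model$bout_rate, 1e-9))
    dur <- stats::rlnorm(1, log(model$bout_duration_s), 0.3)
    if (onset >= n_ms / 1000) break
    bouts[[length(bouts) + 1L]] <- c(onset, min(onset + dur, n_ms / 1000))
    t <- onset + dur
  }
  for (b in bouts) {
    i0 <- max(1L, floor(b[1] * 1000) + 1L)
    i1 <- min(n_ms, ceiling(b[2] * 1000))
    if (i1 <= i0) next
    len <- i1 - i0 + 1L
    amp <- runif(1, model$amplitude_range[1], model$amplitude_range[2])
    f <- model$carrier_freq_hz *
      runif(1, 1 - model$freq_jitter, 1 + model$freq_jitter)
    f <- min(max(f, 6), 60)
    ramp <- min(50L, len %/% 3L)
    env <- rep(1, len)
    if (ramp > 0) {
      up <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
      env[seq_len(ramp)] <- up
      env[len - ramp + seq_len(ramp)] <- rev(up)
    }
    phi0 <- runif(1, -pi, pi)
    ph <- 2 * pi * f * (t_s[i0:i1] - t_s[i0]) + phi0
    envelope[i0:i1] <- pmax(envelope[i0:i1], amp * env)
    phase[i0:i1] <- ph
  }
  if (model$midpoint_drift_sd > 0) {
    noise <- rnorm(n_ms)
    lf <- signal::butter(2, 2 / 500, type = "low")
    drift <- as.numeric(signal::filtfilt(lf, noise))
    s <- sd(drift)
    drift <- if (s > 0) drift / s * model$midpoint_drift_sd else drift * 0
  } else {
    drift <- numeric(n_ms)
  }
  tibble(
    time_ms = seq_len(n_ms) - 1L,
    angle = model$quiet_angle + drift + envelope * cos(phase),
    envelope = envelope,
    phase_true = ifelse(envelope > 0, wrap_pi(phase), NA_real_)
  )
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Simulate a free-whisking angle trace
#'
#' @param model a [whisking_model()].
#' @param duration_s trace duration in seconds.
#' @param seed integer seed; the trace is deterministic given the seed.
#' @return tibble with `time_ms`, `angle` (degrees), `envelope` (ground
#'   truth amplitude, degrees) and `phase_true` (radians, NA outside
#'   bouts).
#' @export
simulate_whisking <- function(model, duration_s, seed = 1) {
  stopifnot(inherits(model, "whisking_model"), duration_s > 0)
  withr::with_seed(seed, sim_whisking_core(model, round(duration_s * 1000)))
}

# Protraction-peak touch extraction for one trial trace.
sim_touches_core <- function(wt, pole_mm, threshold_fun, reach_ms,
                             angle_noise_sd = 0.4) {
  thr <- threshold_fun(pole_mm)
  a <- wt$angle
  n <- length(a)
  peaks <- which(diff(sign(diff(a))) == -2) + 1L
  peaks <- peaks[peaks > reach_ms[1] & peaks < reach_ms[2] &
                   wt$envelope[peaks] > 0 & a[peaks] > thr]
  if (!length(peaks)) {
    return(tibble(onset_ms = numeric(), offset_ms = numeric(),
                  angle_at_touch = numeric(), depth = numeric()))
  }
  onset <- peaks - 1L  # 0-based ms
  dur <- round(runif(length(peaks), 15, 40))
  offset <- onset + dur
  keep <- logical(length(onset))
  last_off <- -Inf
  for (i in seq_along(onset)) {
    if (onset[i] > last_off + 5) {
      keep[i] <- TRUE
      last_off <- offset[i]
    }
  }
  onset <- onset[keep]; offset <- pmin(offset[keep], n - 1L)
  depth <- a[onset + 1L] - thr
  tibble(
    onset_ms = as.numeric(onset),
    offset_ms = as.numeric(offset),
    angle_at_touch = thr + rnorm(length(onset), 0, angle_noise_sd),
    depth = depth
  )
}

#' Simulate one neuron's recording session
#'
#' Trials follow the task structure: a 0.5-s pre-pole period, a 0.75-s
#' stimulus sampling period and a 1.25-s answer period (2.5 s total). Each
#' trial presents the pole at a uniform random location in `pole_range`.
#' Touches are emitted at protraction peaks that exceed a location-mapped
#' angle threshold (`touch_threshold_base + touch_threshold_slope * mm`),
#' so the whisker angle at touch is monotonically coupled to pole location
#' without simulating contact mechanics. Spikes combine an inhomogeneous
#' background process (baseline rate, whisking gain, optional angle/phase
#' tuning) with per-touch responses whose expected count follows
#' [true_touch_lambda()] and whose dispersion matches `count_dispersion`.
#'
#' @param neuron a [ground_truth_neuron()].
#' @param whisking a [whisking_model()].
#' @param n_trials number of trials (> 0).
#' @param pole_range mm interval of presented locations (nonzero width).
#' @param seed integer seed.
#' @param condition `"naive"` or `"trained"` (outcome bookkeeping only).
#' @param session_id character id.
#' @param neuron_depth microns from pia.
#' @param touch_threshold_base,touch_threshold_slope degrees and
#'   degrees/mm of the location-to-angle mapping.
#' @param curvature_scale scale of simulated max curvature change (1/mm).
#' @return a `session_bundle` with attribute `ground_truth` (the neuron,
#'   whisking model, threshold mapping, and per-trial kinematic truth).
#' @export
simulate_session <- function(neuron, whisking = whisking_model(),
                             n_trials = 120, pole_range = c(0, 10),
                             seed = 1, condition = c("naive", "trained"),
                             session_id = sprintf("synth-%04d", seed),
                             neuron_depth = round(runif(1, 600, 950)),
                             touch_threshold_base = 70,
                             touch_threshold_slope = 2,
                             curvature_scale = 0.0015) {
  stopifnot(inherits(neuron, "ground_truth_neuron"),
            inherits(whisking, "whisking_model"), n_trials > 0)
  condition <- match.arg(condition)
  if (diff(range(pole_range)) <= 0) {
    abort("`pole_range` must have nonzero width.")
  }
  dur <- 2500L
  reach <- c(700, 2400)  # pole in touch reach: onset + ~200 ms rise, to near end
  thr_fun <- function(x) touch_threshold_base +
    touch_threshold_slope * (x - pole_range[1])
  withr::with_seed(seed, {
    force(neuron_depth)
    trials <- vector("list", n_trials)
    touches <- vector("list", n_trials)
    spikes <- vector("list", n_trials)
    whisker <- vector("list", n_trials)
    truth_kin <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      pole <- runif(1, pole_range[1], pole_range[2])
      wt <- sim_whisking_core(whisking, dur)
      tt <- sim_touches_core(wt, pole, thr_fun, reach)
      # background spikes: per-ms thinned Poisson with state-dependent rate
      rate <- rep(neuron$baseline_rate, dur)
      whisk <- wt$envelope > 5
      gain <- rep(neuron$whisking_gain, dur)
      if (!is.null(neuron$angle_pref)) {
        gain <- gain * exp(-(wt$angle - neuron$angle_pref)^2 /
                             (2 * neuron$angle_kappa^2))
      }
      if (!is.null(neuron$phase_pref)) {
        ph <- ifelse(is.na(wt$phase_true), 0, wt$phase_true)
        gain <- gain * (1 + neuron$phase_depth * cos(ph - neuron$phase_pref))
      }
      rate[whisk] <- rate[whisk] * gain[whisk]
      k <- rpois(dur, rate / 1000)
      st <- rep(wt$time_ms, k) + runif(sum(k))
      # touch-evoked spikes
      if (neuron$touch_responsive && nrow(tt)) {
        lam <- true_touch_lambda(neuron, pole)
        cnt <- rcount_fano(rep(lam, nrow(tt)), neuron$count_dispersion)
        if (sum(cnt)) {
          ts <- rep(tt$onset_ms, cnt) + neuron$touch_latency_ms +
            runif(sum(cnt)) * neuron$touch_window_ms
          st <- c(st, ts)
        }
      }
      st <- sort(st[st >= 0 & st < dur])
      go <- pole <= mean(pole_range)
      licked <- if (condition == "trained") {
        runif(1) < (if (go) 0.8 else 0.25)
      } else runif(1) < 0.5
      outcome <- if (condition == "trained") {
        if (go) (if (licked) "hit" else "miss")
        else (if (licked) "false_alarm" else "correct_rejection")
      } else "none"
      trials[[i]] <- tibble(
        trial_id = i, duration_ms = dur, pole_location_mm = pole,
        pole_onset_ms = 500, sampling_period_ms = 750,
        answer_period_ms = 1250, licked = licked, outcome = outcome,
        tracked = TRUE
      )
      touches[[i]] <- tibble(
        trial_id = rep(i, nrow(tt)), onset_ms = tt$onset_ms,
        offset_ms = tt$offset_ms, angle_at_touch = tt$angle_at_touch,
        max_curvature_change = curvature_scale *
          (0.5 + tt$depth / 10) * exp(rnorm(nrow(tt), 0, 0.4)),
        direction = rep("protraction", nrow(tt))
      )
      spikes[[i]] <- tibble(trial_id = rep(i, length(st)), time_ms = st)
      whisker[[i]] <- tibble(
        trial_id = i, sample_ms = wt$time_ms, angle = wt$angle,
        masked = FALSE
      )
      truth_kin[[i]] <- tibble(
        trial_id = i, time_ms = wt$time_ms, envelope = wt$envelope,
        phase_true = wt$phase_true
      )
    }
    b <- session_bundle(
      session_id = session_id,
      trials = bind_rows(trials), touches = bind_rows(touches),
      spikes = bind_rows(spikes), whisker = bind_rows(whisker),
      neuron_depth = neuron_depth, condition = condition
    )
    attr(b, "ground_truth") <- list(
      neuron = neuron, whisking = whisking,
      threshold = thr_fun, pole_range = pole_range,
      kinematics = bind_rows(truth_kin)
    )
    b
  })
}

#' Simulate a serially recorded pseudo-population
#'
#' Neurons are recorded in independent sessions (never simultaneously),
#' matching serial single-unit recording; each neuron's parameters come
#' from `neuron_sampler`.
#'
#' @param n_neurons number of neurons (0 gives an empty list).
#' @param neuron_sampler function(i) returning a [ground_truth_neuron()];
#'   the default draws location preferences uniformly over the pole range.
#' @param whisking a [whisking_model()].
#' @param n_trials trials per session.
#' @param pole_range mm interval.
#' @param seed integer seed; session i uses `seed + i`.
#' @param ... passed to [simulate_session()].
#' @return list of `session_bundle`s.
#' @export
simulate_population <- function(n_neurons,
                                neuron_sampler = default_neuron_sampler,
                                whisking = whisking_model(),
                                n_trials = 120, pole_range = c(0, 10),
                                seed = 1, ...) {
  if (n_neurons == 0) return(list())
  lapply(seq_len(n_neurons), function(i) {
    nr <- withr::with_seed(seed + 131071L + i, neuron_sampler(i))
    simulate_session(nr, whisking, n_trials = n_trials,
                     pole_range = pole_range, seed = seed + i,
                     session_id = sprintf("synth-%03d", i), ...)
  })
}

#' Default neuron sampler for [simulate_population()]
#'
#' Draws location preferences uniformly over the 10-mm range with 1-mm
#' tuning SD, baseline rates log-normal around 3 Hz, and per-touch peak
#' counts around 1.5 spikes.
#'
#' @param i neuron index (unused; present for the sampler contract).
#' @return a [ground_truth_neuron()].
#' @export
default_neuron_sampler <- function(i) {
  ground_truth_neuron(
    baseline_rate = stats::rlnorm(1, log(3), 0.4),
    whisking_gain = runif(1, 0.8, 1.6),
    location_pref = runif(1, 0, 10),
    location_sd = 1,
    peak_touch_spikes = runif(1, 1, 2),
    touch_latency_ms = round(runif(1, 6, 20)),
    touch_window_ms = round(runif(1, 8, 30))
  )
}
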