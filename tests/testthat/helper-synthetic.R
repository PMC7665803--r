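# Hand-rolled minimal bundles for fast, controlled tests (no whisking
# dynamics): homogeneous Poisson background with touches on a fixed grid
# and an optional boxcar touch response.

make_touch_bundle <- function(rate_hz = 5, n_touches = 100, latency = NA,
                              window = NA, spikes_per_touch = NA,
                              seed = 1, angle = 70) {
  withr::with_seed(seed, {
    dur <- 2500L
    n_tr <- ceiling(n_touches / 10)
    onsets <- seq(300, 2300, by = 200)[1:10]
    trials <- tibble::tibble(
      trial_id = 1:n_tr, duration_ms = dur, pole_location_mm = 5,
      pole_onset_ms = 500, sampling_period_ms = 750, answer_period_ms = 1250,
      licked = FALSE, outcome = "none", tracked = TRUE
    )
    touches <- do.call(rbind, lapply(1:n_tr, function(i) {
      tibble::tibble(trial_id = i, onset_ms = onsets, offset_ms = onsets + 30,
                     angle_at_touch = 80, max_curvature_change = 1e-3,
                     direction = "protraction")
    }))[1:n_touches, ]
    sp <- lapply(1:n_tr, function(i) {
      s <- sort(runif(rpois(1, rate_hz * dur / 1000), 0, dur))
      if (!is.na(latency)) {
        tt <- touches$onset_ms[touches$trial_id == i]
        k <- rpois(length(tt), spikes_per_touch)
        s <- sort(c(s, rep(tt, k) + latency + runif(sum(k)) * window))
      }
      s
    })
    spikes <- tibble::tibble(trial_id = rep(1:n_tr, lengths(sp)),
                             time_ms = unlist(sp))
    whisker <- tibble::tibble(trial_id = rep(1:n_tr, each = dur),
                              sample_ms = rep(0:(dur - 1L), n_tr),
                              angle = angle, masked = FALSE)
    session_bundle("test-session", trials, touches, spikes, whisker,
                   neuron_depth = 800, condition = "naive")
  })
}

# Per-touch tuning samples straight from a generating Gaussian: stimulus
# uniform over the pole range, counts Poisson at the tuning function.
make_tuning_samples <- function(n = 400, pref = 5, sdev = 1, peak = 1.5,
                                seed = 1, range = c(0, 10)) {
  withr::with_seed(seed, {
    x <- runif(n, range[1], range[2])
    lam <- peak * exp(-(x - pref)^2 / (2 * sdev^2))
    tibble::tibble(stimulus = x, count = rpois(n, lam), lambda = lam)
  })
}
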