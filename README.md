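# whisklocate

Analysis pipeline for single-unit recordings from layer 5 of mouse barrel
cortex during whisker-guided object localization. Head-fixed mice sweep a
single whisker against a vertical pole presented somewhere along a 10-mm
anteroposterior range; the whisker is filmed at 1,000 frames/s and one
neuron is recorded per session. The package answers the questions such
experiments pose: does a neuron encode self-motion (whisker angle or phase
during free whisking)? Does it respond to touch, and is its touch-evoked
spike count tuned to where the pole was? How precisely can a population of
such neurons report pole location? And are the whisking and touch
representations the same neurons with the same preferences, or independent
populations?

It is written tidyverse-style: functions take a data frame (or a
`session_bundle`) first and return tibbles, result objects have
`tidy()`/`glance()` and `autoplot()` methods, and everything chains with
the pipe. A synthetic-session generator with known ground truth makes every
stage testable by parameter recovery.

## The methods in brief

* **Kinematics** — the whisker-angle series `theta(t)` (degrees, 1 kHz) is
  band-passed to the whisking band (6–60 Hz, 4th-order Butterworth, zero
  phase). The analytic signal `z(t)` of the band-passed trace gives
  instantaneous amplitude `|z|` and phase `arg z` (0 = most protracted,
  ±pi = most retracted); the midpoint is the low-passed residual. Whisking
  = amplitude > 5 degrees. Whisking-state rate modulation is tested with a
  1-df chi-squared test of spike counts against time-in-state.
* **Touch responses** — spikes are aligned to touch onsets (−50..+50 ms,
  1-ms bins), the PSTH is smoothed with an adaptive changepoint smoother,
  and the touch-response window is the contiguous span in 5–50 ms
  post-touch exceeding the baseline's 95% band. Touch units must have a
  window of ≥ 4 ms with mean rate > 2 Hz.
* **Tuning curves** — any stimulus (pole location, angle at touch,
  free-whisking angle/phase/amplitude/midpoint/velocity) is binned into 20
  equal-occupancy bins (5% of samples each); response = mean rate in the
  neuron's touch-response window. Significance is a two-step test: one-way
  ANOVA across bins at alpha 0.01, then the observed F must exceed the
  95th percentile of 1,000 label-shuffled F values. Preference = peak of
  the smoothed curve; width via Tukey–Kramer comparisons against the peak
  bin and full width at half maximum; modulation depth = (max−min) and
  (max−min)/(max+min).
* **Decoding** — per-neuron location tuning (expected spike count per
  touch) is interpolated to 40 bins (0.25-mm resolution); 50 Poisson
  samples per bin per neuron form a 2,000-row design. A multinomial
  logistic model with lasso-weighted regularization (mixing 0.95, glmnet)
  is fitted on stratified 70/30 splits for 10 iterations. Outputs:
  confusion matrix, exact-bin accuracy, resolution(n) = fraction of
  predictions within n bins of the truth (n = 2 is ≤ 0.5 mm), neurometric
  lick-probability curves (mass on the posterior "go" half), accuracy
  versus sampled pool size (500 draws with replacement, coefficients
  subset without refitting), and a brute-force Bayes classifier from the
  true Poisson likelihoods as a performance oracle.
* **Independence** — observed co-tuned fraction versus the product of the
  marginal tuned fractions; per-neuron shape correlation of normalized
  whisking- and touch-tuning curves against a curve re-pairing shuffle
  (two-sample KS); distance between whisking and touch preferred angles
  (circular distance for phase).

## Worked example

```r
library(whisklocate)

neuron <- ground_truth_neuron(baseline_rate = 3, location_pref = 4,
                              location_sd = 1, peak_touch_spikes = 1.5)
session <- simulate_session(neuron, n_trials = 120, seed = 42)
session
#> <session_bundle synth-0042: 120 trials, 1072 touches, 1325 spikes, naive, depth 920 um>

profile <- detect_touch_window(session)
profile
#> <touch_profile: touch unit; window 10-26 ms, 28.6 Hz in window, baseline 8.70 Hz, 1067 touches>

curve <- touch_tuning_data(session, profile) |>
  build_tuning_curve(pole_location_mm, rate_hz) |>
  test_tuning(seed = 1) |>
  tuning_width()
glance(curve)
#> # A tibble: 1 x 13
#>   stimulus_name    n_bins n_samples is_tuned F_observed   p_anova F_shuffle_95
#>   pole_location_mm     20      1072 TRUE           40.0 5.62e-110         1.60
#>   preference width_lo_bin width_hi_bin half_max_width abs_mod_depth mod_depth
#>         4.14            7           13           2.47          89.9     0.973
```

The generator placed the tuning peak at 4 mm with 1-mm Gaussian width and
a 10–26 ms response window (latency 10 ms, duration 17 ms): the detector
recovers the window exactly, the two-step test calls the neuron
location-tuned (observed F of 40 versus a shuffle 95th percentile of 1.6),
the recovered preference is 4.14 mm, and the half-max width of 2.47 mm
sits near the Gaussian expectation of 2.355 mm. `autoplot(profile)` and
`autoplot(curve)` draw the PSTH with its detected window and the binned
tuning curve.

Population decoding works the same way from a list of sessions (see
`simulate_population()`, `build_design()`, `fit_decoder()`), and
`compare_to_psychometric()` takes an external psychometric table — a
synthetic stand-in for an expert mouse ships in
`system.file("extdata", "psychometric_expert_synthetic.csv", package = "whisklocate")`.
A thin command-line wrapper over these functions is installed at
`system.file("scripts", "whisklocate", package = "whisklocate")` with
stages `simulate | kinematics | touch | tuning | decode | independence`.

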