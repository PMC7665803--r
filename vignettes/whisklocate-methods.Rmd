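---
title: "Methods: self-motion and object-location coding in barrel cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-motion and object-location coding in barrel cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(whisklocate)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data generator does and does
not emulate. It is the reference for *why* the code does what it does;
the README shows *how* to run it.

## The experimental setting

A head-fixed mouse with a single whisker explores a vertical pole
presented at a random position within a contiguous 10-mm anteroposterior
range. Each 2.5-s trial has a 0.5-s pre-pole period, a 0.75-s stimulus
sampling period and a 1.25-s answer period. The whisker is filmed from
above at 1,000 frames/s and reduced to an azimuthal angle time series
(degrees; larger = more protracted); one neuron is recorded
juxtacellularly per session, so population analyses work on a
*pseudo-population* of serially recorded units. Touch times, the whisker
angle at touch, and the maximum curvature change of each touch are inputs
to the package (video processing and touch detection from images are out
of scope), as are spike times and trial outcomes.

All times are stored in milliseconds from trial start with 0-based
sample indexing; pole locations in mm with 0 at the most posterior
presented position; angles in degrees. These conventions are fixed by the
on-disk bundle format (`write_session()`), which uses one directory of
plain CSV tables per session so fixtures stay inspectable and diff-able.

## Kinematic decomposition

The whisking rhythm lives in a 6–60 Hz band. `hilbert_decompose()`
band-passes the angle series with a 4th-order Butterworth filter applied
forward–backward (zero phase; the order is a conventional choice, stable
at 1 kHz for this band). The mean is removed before filtering: a ~70°
DC offset otherwise leaks large edge transients through `filtfilt`. The
analytic signal of the band-passed trace defines instantaneous amplitude
and phase; phase 0 falls at the protraction maximum of each whisk cycle
and ±π at the most retracted point. The analytic-signal transform is the
standard FFT construction (positive frequencies doubled, negative zeroed)
implemented in-package because no installed package provides it; it is
cross-checked in the tests against the closed form for a pure cosine.

The *midpoint* (slow set-point of whisking) is defined as the residual
`angle − bandpassed`, low-pass filtered below 6 Hz. The published wording
for this quantity is ambiguous; this reading yields the slowly varying
set-point interpretation that the self-motion analyses need.

Whisking is segmented at amplitude > 5°, the same threshold used to mask
phase displays. Two hygiene rules remove chatter at the threshold: gaps
shorter than 50 ms between whisking runs are bridged, and runs shorter
than 50 ms are dropped. Both values are a design choice (about one whisk
cycle at typical carrier frequencies). Segmentation is monotone in the
threshold, and the amplitude envelope upper-bounds the band-passed signal
pointwise — both are tested as properties.

Whisking-state rate modulation (`whisking_rate_comparison()`) uses a
1-df chi-squared goodness-of-fit test of the spike counts in the two
states against expectation proportional to time in state, at alpha 0.01.
The exact chi-squared construction is not pinned down in the original description;
this is the simplest test consistent with its description, and its type-I
behaviour is verified by simulation in the tests. States with under 1 s
of data are flagged undefined rather than tested.

## Touch-response windows

`touch_psth()` pools spikes in 1-ms bins over −50..+50 ms around touch
onsets, excluding touches within 50 ms of a previous touch (response
overlap) and touches too close to trial edges for full support.

The response window is the contiguous span within 5–50 ms post touch
where the *smoothed* PSTH exceeds the upper bound of the baseline's 95%
interval (baseline = −50..0 ms). Two calls were genuinely open and were
made as follows:

* **The smoother.** The reference pipeline uses Bayesian adaptive
  regression splines. The essential property of that smoother is
  *adaptivity*: it returns a nearly flat fit when the data are flat and
  tracks sharp transitions without smearing. Fixed-bandwidth smoothers
  (GCV smoothing splines, penalised GAMs) provably cannot do both here —
  in our simulations they either smeared 5-ms response edges by several
  ms or produced spurious supra-threshold wiggles on featureless PSTHs.
  The stand-in (`psth_segment_smoother()`) is a penalised
  piecewise-constant Poisson segmentation: optimal partitioning by
  dynamic programming under a Poisson likelihood with a BIC-type penalty
  (2 log n per changepoint). It is exactly flat on flat data and places
  changepoints at response edges with millisecond precision. The
  `smoother` argument of `detect_touch_window()` remains a hook for any
  function of `(time_ms, rate)`.
* **The baseline interval.** Whether the 95% CI is across touches or
  across time bins is not specified in the original description. A bootstrap CI of the
  baseline *mean* shrinks as the touch count grows and, at realistic
  counts, sits so close to the mean that chance fluctuations constantly
  exceed it. The implemented band is the 2.5–97.5% range of the
  *smoothed* baseline — so a phase-locked pre-touch whisking oscillation
  widens the band, as it should, since touches occur at protraction
  peaks and the preceding whisk cycle is stereotyped — floored at
  baseline + 1.96 standard errors of a rate estimated over the minimal
  4-ms window, so that perfectly flat baselines are not thresholded at
  their own mean.

If the supra-threshold span is non-contiguous the longest run is taken.
Run edges are then trimmed: a fitted edge segment is kept only if its
pooled spike count is significantly above the baseline expectation for
its length (one-sided exact Poisson test, alpha 0.001 per edge segment).
This guards against chance segments that ride marginally above the band
and would otherwise stretch recovered durations. Residual risk remains —
a background fluctuation that is genuinely significant and contiguous
with the response is, by the definition of the window, part of it — so
window recovery is exact in the typical case but cannot be guaranteed
for every random draw.

A *touch unit* must have a window spanning at least 4 ms with a mean
rate above 2 Hz. The duration gate is implemented as ≥ 4 ms (duration =
count of supra-threshold milliseconds): observed real-population
durations extend down to exactly 4 ms, so a strict "greater than" would
exclude data the criterion was built from; a 3-ms elevation is still
rejected. Windows are confined to 5–50 ms post touch, so latency +
duration combinations extending past 50 ms are truncated by
construction.

## Equal-occupancy tuning curves

`build_tuning_curve()` sorts samples by stimulus (stable sort; ties at
bin boundaries break by input order), partitions them into 20 bins of
equal occupancy (sizes differ by at most one; 5% of samples per bin),
and summarises each bin by median stimulus and mean response. Touch
curves use the rate in the neuron's detected response window; non-touch
units fall back to the 10–28 ms population-median window, which is also
the integration window for free-whisking tuning (each whisking
millisecond contributes the rate in the window offset from that time
point). Whisking curves are only evaluated when the mean whisking
response reaches 2 Hz. Curves need at least 40 samples (two per bin).

The curve smoother here is a GCV smoothing spline evaluated at the 20
bin medians — with 20 averaged points the adaptivity concerns above do
not apply — and max/min for modulation depths are read from the smoothed
values at the bin medians, not a dense grid.

Significance is the two-step procedure: one-way ANOVA across bins at
alpha 0.01, then 1,000 label permutations of the raw responses with the
observed F required to exceed the shuffled 95th percentile. The
permutation F statistics are computed by a vectorised group-sum routine
(verified in tests against `stats::oneway.test(var.equal = TRUE)`), with
shuffles chunked so memory stays bounded for whisking curves with 10^5
samples. Degenerate inputs (all responses equal) give an undefined F and
are not tuned.

Width has two readouts: the first bins on each side of the peak whose
responses differ from the peak bin under a Tukey–Kramer critical value
(the studentised range at a 0.95 family level over the 20-bin family;
the family and level are a documented assumption), and the full width at
half maximum of the smoothed curve on a dense interpolation, which for a
Gaussian tuning profile of width sigma should approach 2.355 sigma.

`stratified_tuning()` median-splits each bin by a covariate (max
curvature change) to control location tuning for touch strength; bins
with fewer than 4 touches are excluded and a constant covariate is an
error. `fano_per_bin()` reports the per-bin variance-to-mean ratio of
spike counts, the quantity that justifies Poisson resampling in the
decoder.

## Population decoding

Only touch units with at least 75 touches covering at least 80% of the
binned pole locations enter the decoder. Each included neuron's 20-bin
location curve (expected spike *count* per touch — counts, not rates,
are what the Poisson justification is stated on) is interpolated to 40
bins at 0.25-mm spacing with a monotone (Fritsch–Carlson) piecewise
cubic, clipped at zero and clamped to the observed stimulus range. At
each bin, 50 Poisson draws per neuron give a 2,000-row design.

The decoder is a multinomial logistic model with elastic-net mixing 0.95
(lasso-dominated), fitted with glmnet; the regularisation strength is
chosen by cross-validation on the training split (the original analysis fixes only
the mixing). Ten iterations each draw a random 70/30 train/test split,
stratified by location bin so every class appears in both splits;
accuracy and the row-normalised confusion matrix are averaged over
iterations. Whether the ten iterations should also re-draw the Poisson
design is not specified; both modes exist (`redraw`), with re-split-only
the default. Predictions are softmax argmax with ties broken toward the
lower bin, deterministically.

Readouts: resolution(n) = fraction of predictions within n bins of the
diagonal (n = 2 is ≤ 0.5 mm); neurometric lick probability per true
location = predicted mass on the go half of the confusion matrix (the
posterior 20 bins, configurable), with simulated licks wherever that
probability exceeds 50%; and accuracy versus sampled pool size, where
pools are drawn with replacement 500 times and both the design columns
and the corresponding learned coefficients are subset without refitting.

`bayes_location_decoder()` is the performance oracle: exact Poisson
maximum-likelihood classification with the generating lambdas. The
fitted decoder should approach but not beat it. One honest caveat,
established by a sweep of the entire regularisation path (and
class-based cross-validation, grouped penalties, and unstandardised
fits): at 40 classes and 35 training draws per class the multinomial
model's *exact-bin* accuracy plateaus several percentage points below
the oracle — the estimation noise of roughly a thousand coefficients is
irreducible at this design size — while the ≤ 0.5-mm resolution agrees
closely. `design_from_lambda()` builds the oracle-benchmark design
directly from known tuning functions so that curve-estimation noise does
not enter the comparison.

`compare_to_psychometric()` takes the behavioural reference as an
external table (mean ± SD lick probability per location, with subject
count); no real behavioural data are bundled, and a clearly labelled
synthetic stand-in ships in `inst/extdata/`.

## Independence analyses

The expected co-tuned proportion under independence is the product of
the marginal tuned proportions; the observed proportion always lies in
the Fréchet interval `[max(0, p_w + p_t − 1), min(p_w, p_t)]`, and both
are reported in percent. Shape correlation compares min–max-normalised
whisking and touch curves resampled to a 20-point grid on the
intersection of their stimulus supports (grid and normalisation are
documented choices); the null re-pairs curves across neurons by a
permutation, which preserves each marginal curve set exactly — the
permutations used are returned so this invariant can be asserted — and a
two-sample Kolmogorov–Smirnov test compares observed and shuffled
correlation distributions. Preference displacement uses the absolute
difference for angle (the whisking range is far from circular closure)
and circular distance (in [0, π]) for phase.

## The synthetic-session generator

`simulate_session()` exists so every stage can be tested by parameter
recovery; its defaults are the study conditions. Trials follow the
0.5/0.75/1.25-s epoch structure at 1 kHz. Whisking is a renewal process
of bouts (1 bout/s, log-normal durations around 0.7 s), each carrying a
constant-frequency carrier (16 Hz ± 15% jitter, inside the 6–60 Hz band)
under a raised-cosine envelope with per-bout amplitude uniform on
12–28°, over a < 2 Hz midpoint drift (SD 2.5°) around a 70° set-point.
Sessions default to 120 trials, within the reported range of trials held
per neuron; together these defaults yield several hundred touches per
session covering over 80% of binned pole locations, so the decoder's
inclusion rule is attainable — no touches-per-trial distribution is reported for the original sessions
distribution, so these are the package's choices.

Touches are emitted, without any contact mechanics, at protraction peaks
that exceed a location-mapped angle threshold (70° + 2°/mm): the angle
at touch is then monotonically coupled to pole location (correlation
above 0.9), which is the only property downstream analyses need. The
2°/mm slope is a generator convention chosen so the full 10-mm range is
reachable by a realistic whisking envelope. Max curvature change is a
noisy increasing function of how far the peak overshoots the threshold,
so it correlates only weakly with location and the strength-stratified
control is exercisable.

Spikes combine a background inhomogeneous Poisson process — baseline
rate, multiplied during whisking by a gain and optional Gaussian angle
tuning and cosine phase tuning — with per-touch responses: the expected
count per touch follows a Gaussian over pole location
(`true_touch_lambda()`), spread uniformly over the response window at
the set latency. Count dispersion is a knob: Poisson at Fano 1, negative
binomial above, and binomial (n = ceiling(mu/(1−F)), p = mu/n) below;
the default 0.94 matches the near-Poisson dispersion of real touch
responses.

What the generator does **not** emulate — and hence what passing
recovery tests do and do not show about real data: no whisker mechanics
or curvature dynamics (curvature is a statistical stand-in); whisking
does not react to the pole (real mice adapt their midpoint); touch
responses are boxcar in time rather than shaped; background and touch
processes are conditionally independent given the kinematics; and
sessions are stationary. Recovery results therefore validate the
*estimators* under the stated statistical model, not the biology.

## Problem sizes and determinism

The test-suite and acceptance problem sizes are chosen to make
statistical assertions meaningful while staying lightweight: 400 touches
per synthetic tuning curve (matching a typical session), 50 neurons for
preference recovery, 1,000 simulations for each calibration claim
(two-step tuning test at alpha 0.01; touch-unit false positives), a
25-neuron population with 10 decoder iterations and 500 subsampling
draws per pool size, and 20-s traces for segmentation recovery. All
randomness flows through explicit seeds (`withr::with_seed`), so every
number in the acceptance report is reproducible from `--seed`.

## Known limitations

* The bundle format is a package convention; no reader for the original
  lab's MATLAB structures is provided.
* BARS itself is not implemented; the segmentation smoother is a
  documented stand-in with the same adaptivity, selected for recovery
  behaviour, not smoother identity.
* The exact-bin decoder-versus-oracle gap discussed above.
* Phase tuning is analysed with the same linear binning as angle
  (matching the reference procedure); no circular statistics beyond the
  circular preference distance.
* The behavioural psychometric curve is consumed, never fitted.
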