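---
title: "Memory-guided saccade analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-guided saccade analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsaccade)
```

The memory-guided saccade task (MGST) probes spatial working memory and
oculomotor inhibition: the subject fixates a central dot, a peripheral target
flashes briefly, fixation must be held through a memory interval, and only
when the central dot disappears (the "go" signal) may the eyes move to the
*remembered* target location. A confirmation dot then appears at the true
location and the subject corrects any landing error with a visually guided
saccade (VGS). This package implements the full analysis chain for such
recordings — and a synthetic gaze generator so that every stage can be
validated against known ground truth.

## Task geometry and paradigm

The display model (`screen_geometry()`) assumes square pixels; the physical
panel width follows from the diagonal (584.2 mm for a 23-inch panel) and the
16:9 aspect ratio, giving a pixel pitch of about 0.265 mm at 1920 x 1080.
Visual angle of a gaze *position* is `atan(offset_mm / distance)`: positions,
not extents, are converted, so the single-arctangent form is used rather than
the `2 atan(d/2D)` subtense form; below 20 degrees the difference is under
0.01 degrees. At a 650 mm viewing distance 100 px corresponds to about 2.34
degrees, and the 10/18-degree targets sit about 432 and 796 px from centre.

A trial (`paradigm_spec()`) is six intervals: central fixation 1500 ms,
target flash 200 ms, memory 1300 ms, reaction 1500 ms, confirmation 2500 ms,
inter-trial blank 700 ms — 7700 ms in all. Ten trials for each of the four
target positions (left/right x 10/18 degrees) give a 40-trial session of
about 5.1 minutes. Trial order is a seeded uniform shuffle with no run-length
constraint (nothing in the task requires one); `trial_schedule()` is exactly
balanced for every seed.

## The synthetic gaze generator

`simulate_session()` emulates a 250 Hz binocular recording. Its components,
and what they do and do not capture:

* **Saccade waveforms** are minimum-jerk position profiles. Peak velocity
  follows the classic amplitude main sequence
  `Vpeak = vmax (1 - exp(-A / c))` with defaults `vmax = 500` deg/s and
  `c = 14` deg. A minimum-jerk profile of amplitude A and duration T peaks at
  `1.875 A / T`, so duration is derived as `T = 1.875 A / Vpeak`. We
  deliberately do *not* also impose the common linear duration rule
  (`2.2 A + 21` ms): for a single unimodal velocity profile the two rules are
  jointly unsatisfiable at small amplitudes (below roughly 8 degrees the
  linear rule would demand a mean velocity exceeding the main-sequence peak),
  and the peak-velocity law is the one the detection metrics depend on. The
  resulting durations (about 73 ms at 10 degrees) are physiological.
* **Outcomes** are drawn per trial from the profile probabilities using a
  single uniform per trial partitioned early / late / omission / valid, so
  enlarging a probability enlarges the corresponding outcome set under a
  shared seed — the monotonicity tests rely on this. Error trials break
  fixation toward the flashed target; early errors are drawn 80–280 ms after
  flash onset and late errors from 330 ms, leaving a guard band around the
  300 ms early/late boundary so that ground-truth labels remain unambiguous
  under 4 ms sampling and detector quantisation. (The classifier itself uses
  the exact 300 ms boundary; the guard band is purely a property of the
  generator.)
* **Fixation noise** is a per-eye AR(1) process with stationary SD
  `fixation_noise_sd` (default 0.3 deg, a typical screen-tracker accuracy)
  and coefficient 0.98. White noise of that magnitude would be wrong: at
  250 Hz it would push ~14% of 20 ms windowed velocities above the 30 deg/s
  threshold, which real trackers with 0.3-degree accuracy do not do — their
  error is strongly autocorrelated (drift plus tremor). The AR(1) choice
  reproduces the stationary accuracy figure while keeping sample-to-sample
  jitter realistic.
* **Blinks** are runs of invalid samples in both eyes (truncated-normal
  duration, default 150 +/- 40 ms, at most one per trial); the pipeline only
  consumes validity semantics, so no vertical eyelid artefact is modelled.
* **Binocularity** is the cyclopean signal +/- half a constant interocular
  offset plus independent per-eye noise. Vergence dynamics, pupil size,
  vertical saccades, smooth pursuit and head motion are *not* modelled —
  passing tests say nothing about those aspects of real data, nor about
  calibration error, which is absent by construction.

`simulate_cohort()` adds a subject level: covariates (age, gender, MoCA,
HADS, Color Trails, Digit Span, processing-speed scores) with truncated
normal or Bernoulli marginals, and per-subject generating parameters
(latencies, gain, vmax, error probabilities) that vary around the baseline
profile. Dependence is induced by a Gaussian copula *on the generating
parameters*, never on computed outputs, so downstream recovery is a genuine
end-to-end test; target Spearman correlations are mapped to latent Pearson
correlations via `2 sin(pi rho / 6)` and the implied matrix is checked for
positive semi-definiteness. Deterministic links (e.g. a linear age effect on
the late-error probability) are available for slope-recovery experiments.
Because the observable error *rate* adds binomial trial noise on top of the
between-subject parameter spread, an induced parameter-level correlation
appears attenuated in the rates by the classical reliability factor
`sd(p) / sqrt(var(p) + mean(p(1-p)/n))`; the tests account for this
explicitly. The default between-subject spreads (e.g. SD 0.12 for the
late-error probability) were chosen once so that between-subject variation
dominates the binomial noise of a 40-trial session, as it must for any
cohort in which rate correlations are detectable at all.

## Preprocessing

Three stages mirror a standard velocity-threshold (I-VT) filter chain:

1. **Gap fill** (`fill_gaps()`): runs of invalid samples up to 75 ms, flanked
   by valid samples, are linearly interpolated per eye; longer runs and runs
   touching the recording edges stay invalid. Interpolated samples count as
   valid downstream — that is the purpose of gap filling. The operation is
   idempotent.
2. **Eye averaging** (`average_eyes()`): mean of the two eyes' pixel
   positions where both are valid, the single valid eye otherwise, invalid
   where neither. No smoothing is applied (noise reduction disabled).
   Positions convert to degrees from screen centre.
3. **Windowed velocity** (`angular_velocity()`): the angular separation of
   the positions at the two ends of a 20 ms window divided by the window
   duration. At 250 Hz the 20 ms window spans 5 sampling intervals, split
   2 back / 3 forward around the sample (a perfectly centred split does not
   exist on this grid). Separation is Euclidean in (x, y) degree space —
   standard in I-VT implementations; the exact spherical angle differs
   negligibly below 20 degrees. Velocity is undefined wherever any window
   sample is invalid or out of range; for a constant-velocity segment the
   windowed value equals the instantaneous one exactly. A 20 ms boxcar
   attenuates the peak of a 10-degree minimum-jerk saccade by about 5%; the
   tests compare the detector against the windowed-operator oracle, not the
   instantaneous peak.

## Event detection and its post-filters

`ivt_classify()` labels maximal runs of samples at or above 30 deg/s as
saccades (the threshold comparison is inclusive — a sample at exactly
30 deg/s is saccadic, matching common filter conventions), runs below as
fixations, and undefined-velocity or invalid runs as gaps; undefined samples
flanking true gaps therefore terminate events, which keeps segmentation
conservative. A saccade's offset is its last above-threshold sample plus one
sample period; amplitude is the start-to-end angular separation, mean
velocity the mean of per-sample velocities, and time-to-peak the
onset-to-argmax interval.

`merge_fixations()` merges consecutive fixations separated by at most 75 ms
with centroids at most 0.5 degrees apart, absorbing whatever short saccades
or gaps lie between them (vendor-style behaviour); the pass iterates left to
right until stable and weights merged centroids by duration.
`enforce_min_fixation()` then relabels fixations shorter than 60 ms
(inclusive bound: exactly 60 ms is kept) as "unknown".

A consequence worth knowing: the detected onset of a saccade lags its true
onset by the time the velocity takes to reach threshold. For a minimum-jerk
profile that is `tau_c T` with `16 tau_c^2 (1 - tau_c)^2 = threshold/Vpeak`
— a few ms for 10-degree saccades but up to ~15 ms for 1.5-degree corrective
saccades. Latency estimates for small saccades inherit this bias; it is a
property of every velocity-threshold detector, not of this implementation.

## Trial gating, selection and the error taxonomy

A trial enters analysis (`validate_trial()`) only if, throughout the 60 ms
window ending at flash onset, every sample is valid, no saccade event
overlaps the window, and horizontal gaze stays within +/-100 px of centre.
The window form was preferred over a single-instant check at -60 ms as the
more robust reading (it contains the instant). Violations are reported in
the order blink, saccade, off-centre.

Errors (`classify_error()`) are saccades of at least 1 degree made during
the memorisation phase (flash onset to the end of the memory interval — the
natural end of the "hold fixation" requirement): early if onset is within
300 ms of flash onset (inclusive), late after. The boundary is configurable.
Error saccades carry no clean-history or start-band requirement — they are
fixation breaks, not analysed saccades; only the amplitude floor keeps noise
out of the counts.

The memory-guided saccade (`extract_mgs()`) is selected by a strict
first-saccade rule on the reaction interval: the first saccade is accepted
iff its amplitude is >= 1 degree, its start lies inside the +/-100 px band,
it moves toward the cued side, and the preceding 100 ms contain no saccade
or gap; otherwise the trial is an omission, with no fallback to later
saccades. The direction requirement is our addition (a saccade away from the
cue is not a saccade "toward the remembered location"); it can be switched
off in the configuration. The corrective VGS (`extract_corrective_vgs()`)
applies the same first-saccade logic to the confirmation interval, requiring
that the movement reduce the distance to the now-visible target; its latency
anchor is confirmation onset, and its gain is computed against the distance
it had to cover (target minus start position) so that 100 again means a
perfectly sized movement.

Seven metrics are computed per accepted saccade: latency, amplitude,
duration, mean velocity (mean of per-sample windowed velocities; an
amplitude/duration variant would differ only through the window), peak
velocity, time to peak, and gain = amplitude / target amplitude x 100.
Velocities are kept in deg/s throughout; a deg/ms reading is a unit relabel
(x 1e-3) left to the caller.

`summarize_subject()` aggregates per subject: `%MGS` uses *all* session
trials as denominator while `%CorrVGS` and the three error rates use *valid*
trials — the denominators are deliberately asymmetric, following the
indicator definitions, and `%TotalError = %Early + %Late` holds exactly.
Means and sample SDs (n-1) of the seven metrics are computed separately for
near (10 degree) and far (18 degree) targets and for MGS vs VGS. Subjects
with fewer than 7 valid trials are flagged excluded; with zero valid trials
the valid-denominator rates are undefined rather than zero.

## Statistical layer

`correlate_all()` computes Spearman (default) or Pearson correlations
between every oculomotor summary column and every covariate, pairwise
complete, dropping pairs with fewer than 3 observations. Spearman p-values
use the t approximation `t = rho sqrt((n-2)/(1-rho^2))` with average ranks
for ties. Raw p-values are flagged at alpha = 0.05 with no multiplicity
correction by default — the analysis this mirrors reported raw p-values —
and a Benjamini–Hochberg option is available but off.

`fit_late_error_regression()` is ordinary least squares of the late-error
rate on age, gender (0 = female, 1 = male, so a positive coefficient means a
higher male rate), MoCA total, HADS anxiety and depression, and Color Trails
1 time and errors — seven predictors, listwise complete cases, F on
(7, n-8) df. Assumption diagnostics: Breusch–Pagan (homoscedasticity) and
Durbin–Watson (independence) via lmtest, Jarque–Bera (residual normality)
computed from sample skewness and kurtosis, a residual-versus-fitted
quadratic term as the linearity check, and `vif()` — the diagonal of the
inverse predictor correlation matrix, i.e. `1/(1 - R2_j)` — for
multicollinearity, with perfectly collinear predictors reported as infinite.
Rank-deficient designs are rejected with the offending predictor named.

## Numerical and interface choices

* Timestamps are integer milliseconds on the 4 ms grid (exact in floating
  point); all interfaces speak milliseconds.
* The gaze TSV dialect (`read_gaze_tsv()` / `write_gaze_tsv()`) is
  project-defined with fixed column names, since vendor export schemas vary
  across software versions; positions are written with four decimals so a
  read-write cycle of a canonical file is byte-identical. Schedules and
  covariates travel as CSV, ground truth as JSON, configuration as YAML
  (`config_to_yaml()` round-trips losslessly).
* Every stochastic entry point takes a seed and restores the caller's RNG
  state; the whole simulate-process-summarise-stats chain is bit-reproducible
  given a configuration and seed.
* Degenerate inputs fail loudly: non-finite offsets, angles beyond 90
  degrees, windows shorter than two sample periods, zero target amplitudes,
  unknown configuration fields, infeasible copula targets.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make sampling bands
meaningful while staying desk-sized: single 40-trial sessions for exact
recovery checks; 1000 trials (25 sessions) for binomial rate recovery; a
200-subject cohort for slope and rank-correlation recovery; and, for the
null calibration of the correlation tests, 200 cohorts of 15 subjects with
shortened 12-trial sessions, pooling 2000 p-values — the binomial 95% band
around the nominal 5% rejection rate at that count is roughly 4.0–6.0%.

## Known limitations

* The generator's saccades are noiseless minimum-jerk trajectories; real
  saccades show post-saccadic oscillations, glissades and curvature, none of
  which the detector is stressed with here.
* Latency estimates inherit the threshold-crossing lag discussed above;
  comparisons across amplitude classes should keep it in mind.
* The covariate marginals are plausible for an older clinical cohort but are
  not fitted to any dataset; only their correlation structure with the
  oculomotor parameters is controlled.
* The statistical layer reproduces the analysis design (raw p-values, seven
  fixed predictors); it does not attempt model selection or mixed-effects
  trial-level modelling.
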