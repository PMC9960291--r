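---
title: "Estimating mechanical loading from accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mechanical loading from accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpload)
```

## Overview

`jumpload` estimates the mechanical loading of the skeleton during jumping
exercise from body-worn accelerometers. The pipeline mirrors laboratory
practice: raw triaxial signals from a force plate (1000 Hz, newtons) and
from accelerometers at the ankle, lower back and hip (100 Hz, g) are
processed into per-jump impact events, each event contributes a peak ground
reaction force (pGRF), peak loading rate (pLR), peak acceleration (pACC)
and peak acceleration rate (pAR), and per-trial means of these feed either
the fixed-coefficient prediction equations in the registry or the
model-development and validation machinery.

This vignette explains the processing model and its assumptions, the
parameters a user can reasonably touch, what the synthetic data generator
does and does not emulate, and the numerical decisions embedded in the
code.

## The processing chain

Processing order is fixed: **resample → filter → reduce to one channel →
synchronize → detect peaks → rates → summarize**.

1. **Resampling.** The force signal is downsampled to the accelerometer
   rate (default 100 Hz) by linear interpolation on each axis. Linear
   interpolation rather than decimation-with-antialiasing is deliberate:
   the low-pass filter comes *after* resampling in this chain, so it
   handles any aliased content, and interpolation keeps impact-peak
   amplitudes closer to the raw recording. Upsampling is refused.

2. **Filtering.** A 4th-order Butterworth low-pass at 20 Hz, applied
   forward and backward (zero phase) on each axis component. Zero-phase
   filtering matters because the synchronization step operates at
   single-sample (10 ms) resolution, which the group delay of a one-pass
   IIR filter would corrupt. The effective attenuation is the square of a
   single pass; the cutoff is *not* order-corrected for the double pass.
   Whether to filter the axis components (and then take the norm) or the
   resultant itself is genuinely open; the package defaults to components
   (`filter$stage = "components"`) and exposes the alternative
   (`"resultant"`). The difference is small because the resultant of these
   signals is dominated by the vertical component.

3. **Channel reduction.** Either the resultant vector
   `r_i = sqrt(x_i^2 + y_i^2 + z_i^2)` or, for vertical-vector analyses,
   the rectified axis aligned with the body's longitudinal direction
   (`vertical_axis`, default `"z"`). Rectification makes impact peaks
   positive regardless of sensor orientation convention.

4. **Synchronization.** The two streams are first aligned by their
   recorded clocks (the `t0` difference rounded to the nearest sample);
   the residual is then found by maximizing the normalized
   cross-correlation of the mean-removed signals over lags within ±5 s of
   the clock alignment. The reported lag is the accelerometer's delay
   relative to the force plate. Ties break toward the smallest residual
   lag, then toward the negative one. The correlation *magnitude* is
   maximized and the signed value reported, so an inverted channel
   surfaces as `peak_xcorr ≈ -1` for the caller to deal with — no silent
   auto-inversion. The interactive visual adjustment used in laboratory
   practice is replaced by an explicit `manual_offset_s` configuration
   value, recorded separately in the result.

5. **Peak detection.** A sample is a candidate impact if it is a local
   maximum strictly above the trial mean plus 3 standard deviations (SD
   with the n−1 denominator, computed over the whole filtered trial —
   the threshold is trial-relative, so adding a constant to the signal
   changes nothing). Candidates closer together than the minimum
   separation (0.2 s for continuous jumps, 4 s for drop and box jumps)
   are resolved greedily by descending magnitude, ties to the earlier
   index: of a close cluster only the largest peak survives. The greedy
   rule is an implementation choice — any deterministic rule satisfying
   the separation criterion would do — selected because it is
   order-independent and easy to audit.

6. **Force matching and rates.** The force peak for each acceleration
   peak is the largest force sample within ±0.2 s (continuous) or ±4 s
   (drop, box), clipped to the signal bounds, earliest sample on ties.
   Rates use the centered first difference
   `f'_i = (f_{i+1} - f_{i-1}) / (t_{i+1} - t_{i-1})`, exact for linear
   and quadratic sequences; the two boundary samples are dropped rather
   than patched with one-sided differences. pLR and pAR are the maximum
   of this derivative between contact onset and the peak. Contact onset
   is not defined numerically in the source literature; the package
   operationalizes it as the last pre-peak sample below
   `max(20 N, 2 % of the peak)` for force, or within ±0.2 g of the trial
   median for acceleration, searched up to 1 s before the peak with the
   window start as fallback. All three thresholds are configuration
   keys.

7. **Summaries.** Arithmetic means of pACC, pAR, pGRF and pLR over a
   trial's matched events, one row per subject × jump type × height ×
   placement × vector.

## The prediction equations

The registry holds twelve immutable equations of the form
`b0 + b1·p + b2·m + b3·p·m` (predictor `p`: pACC in g for pGRF, pAR in g/s
for pLR; `m`: body mass in kg; output N or N/s). The units contract is
worth stating prominently because the equations are numerically meaningless
in m/s²: acceleration enters in gravitational units. Negative predictions
at implausible inputs are possible, returned unclamped with a warning flag;
clamping would silently distort downstream validation statistics.

## Model development and validation

The mixed model behind each equation regresses the outcome on the
predictor, body mass and their interaction as fixed effects, with random
intercepts for subject and for the jump-type-by-height combination (encoded
as one concatenated grouping factor). Estimation is by maximum likelihood
by default — −2 log-likelihood comparisons across fixed-effect structures
require ML — with REML available by flag. Convergence and singularity
messages are captured on the result object rather than raised, because a
singular fit on degenerate (for instance noiseless) data is still a usable
fit.

Conditional R² follows the Nakagawa–Schielzeth formulation:
`(var_fixed + var_random) / (var_fixed + var_random + var_residual)`, with
`var_fixed` the variance of the fixed-effect linear predictor over the
data.

Cross-validation is subject-wise leave-one-out: each subject's rows are
held out once, the model is refit with the same specification, and the
held-out rows are predicted from the fixed effects only. A subject unseen
at training time has no estimable random intercept, so fixed-effects-only
prediction is the only defensible choice; it also mimics how the published
equations are applied to new people. Folds that fail to refit are marked
and skipped; more than 10 % failures aborts.

Agreement analysis defines differences as actual − predicted throughout.
The report carries the bias, bias ± 1.96 SD limits of agreement, a
one-sample t-test of the differences, an OLS regression of difference on
pairwise mean (proportional bias; two-sided test at α = 0.05), MAE, MAPE
and RMSE (each reported with the SD of the per-row errors), and the
percentage of points inside the limits. Zero-variance differences make the
t-test and the proportional-bias regression undefined; they are reported
as `NA` with a `degenerate` flag and the plot still renders.

## The synthetic data generator

No human data ship with the package, so every claim its tests make is
grounded in a simulator with known truth. `protocol_spec()` encodes the
emulated protocol: 78 subjects with body mass drawn from a truncated
Gaussian (mean 82.4 kg, SD 20.6 kg, range 45–160 kg), drop jumps from
5–40 cm in 5 cm steps and box jumps at 5/15/30 cm (eight landings per
condition), and 20 s of continuous jumps at 5 and 15 cm.

The waveform model: quiet standing at body weight `m·9.807` N; flight
phases near 0 N with smooth (raised-cosine/smoothstep) edges; each landing
an asymmetric double pulse — a passive impact spike (gamma-shaped, peak at
50 ms) plus an active push-off hump (peak at 220 ms) — with amplitude
proportional to body mass and increasing with impact velocity
`v = sqrt(2·g·h)`. Acceleration at each placement is the same time-locked
transient on a 1 g standing baseline, scaled by a placement gain (ankle
3.5, hip 2.6, lower back 2.4 g per m/s of impact velocity, reproducing the
ankle > hip ≈ lower back ordering of real recordings), delayed by a
per-trial clock offset rounded to a whole accelerometer sample, and
overlaid with white sensor noise (0.02 g per axis; force noise 4 N per
axis). Sharing the pulse timing and spike/hump mix between the force and
acceleration channels keeps the paired signals time-locked, which is what
makes the injected clock offset identifiable to the sample — and is also
roughly what rigid-body physics implies for the body's centre of mass.
The continuous-jump cycle is 1.2 s (16 landings per 20 s set), a typical
rebound-jumping cadence.

Ground truth (landing times, per-jump peak force and loading rate,
per-placement peak acceleration and rate, the clock offset, body mass) is
measured on the noiseless sampled waveforms before noise is added.

Randomness discipline: one root seed; every per-subject and per-trial
stream derives its own child seed from (subject, condition, stream)
indices, so regenerating with more subjects leaves existing subjects'
draws untouched, and the same spec always produces byte-identical fixture
bundles.

**What the simulator does not emulate.** Waveform realism is qualitative
only: real landings differ between feet, vary jump to jump, and show
placement-specific frequency content; real continuous-jump cadence drifts;
real acceleration-to-force coupling is not an exact affine map, so real
cross-correlation synchronization can be off by a sample or two (the
reason the laboratory protocol included a manual adjustment step, and the
reason `manual_offset_s` exists). Passing tests therefore demonstrate that
the *algorithms* are correct against injected truth — they do not
demonstrate field accuracy on human data, which is what the published
accuracy indices (MAPE ≈ 12–25 % depending on outcome and placement)
describe.

`simulate_summary_table()` skips the waveform level entirely and generates
per-trial summary rows directly from the mixed model
`y = b0 + b1·p + b2·m + b3·p·m + u_subject + v_condition + e` with all
latent draws recorded — the right level for testing estimation,
cross-validation and agreement machinery.

## Numerical choices

- **Filter implementation.** Coefficients come from `signal::butter`; the
  forward–backward pass is implemented in the package as a
  direct-form-II-transposed recursion with steady-state initial
  conditions (the classic step-response initialization, obtained by a
  small linear solve) and odd-reflection padding of `3·(order+1)` samples
  per end. This combination makes the DC gain exactly 1 on constant
  signals and suppresses edge transients on short jump trials.
- **Sampling-uniformity tolerance.** Readers infer the rate from the
  median time step and reject files whose steps deviate from it by more
  than 1 part in 10³ — tight enough to catch corrupt files, loose enough
  for float-formatted timestamps. Inferred rates within 1e-4 of an
  integer are snapped to it, since absolute epoch-seconds time columns
  quantize the step at ~1e-7 relative.
- **Serialization.** All numeric CSV output uses 17 significant digits,
  so write → read is the identity on IEEE doubles.
- **Derivative boundaries.** The centered derivative drops its two
  boundary samples; peaks never sit at trial boundaries in practice, and
  one-sided differences would silently have different error properties.
- **Tie-breaks.** Peak suppression: descending magnitude, earlier index
  first. Force matching: earliest sample. Synchronization: smallest
  residual lag, then negative.
- **Degenerate inputs.** Zero-variance signals yield an empty peak list
  (not an error) but refuse to cross-correlate; zero-variance differences
  flag the agreement report as degenerate; noiseless mixed-model fits
  carry their convergence messages instead of failing.

## Problem sizes used by the test suite

The suite exercises the full study geometry where it matters — parameter
recovery runs 20 replicates of 78 subjects × 13 conditions, and LOOCV
correctness is verified at up to 78 folds in the acceptance script — while
pipeline-level signal tests use shortened trials (3–4 landings instead of
8) and a handful of subjects, which preserves every code path at a
fraction of the signal length. Peak-recovery and synchronization checks
run on 50 and 100 freshly simulated trials respectively.

## Known limitations

- The loading-rate truth is defined on the native 1000 Hz waveform, while
  the pipeline (matching the published flowchart) computes rates on the
  resampled, filtered 100 Hz signal; the pipeline's pLR is accordingly
  lower by tens of percent on sharp transients. This mirrors a real
  limitation of 100 Hz accelerometry noted in the source literature, not
  an implementation defect.
- Jump-type classification is out of scope: the pipeline must be told
  what kind of trial it is processing, because the separation and
  matching windows depend on it.
- The equations are for jumping in adults; applying them to other
  movements or populations is extrapolation.
- The vendor dialect covers the header layout this package writes and
  parses; binary vendor containers are out of scope.
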