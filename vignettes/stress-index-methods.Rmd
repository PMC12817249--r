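---
title: "Composite stress indices from a wearable biomarker panel: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite stress indices from a wearable biomarker panel: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressci)
library(dplyr)
```

# The problem

Mental stress leaves a physiological signature in quantities a wearable
device can measure non-invasively: sweat cortisol (nM), sweat glucose (uM),
skin temperature (ST, degrees C) and heart rate (HR, bpm). Turning that
four-biomarker panel into a usable stress readout runs into two obstacles:

1. **Inter-individual differences** — absolute biomarker levels vary widely
   between people, so raw values are not comparable across subjects.
2. **Intra-individual circadian variation** — cortisol follows a pronounced
   daily rhythm and glucose follows meals, so raw values are not comparable
   across clock times either.

`stressci` implements a graded response to both: an unweighted
relative-change index for within-session acute monitoring, a
regression-weighted, circadian-corrected index for acute-stress (AS)
classification, and a machine-learning stage for chronic-stress (CS)
assessment. Because the underlying clinical data are not public, the
package ships a seeded synthetic-cohort generator that reproduces the
statistical structure each stage assumes, so that every stage is testable
end to end.

# The three indices

## Unweighted relative-change sum

For a measurement vector $m$ and a control vector $c$ (the values before a
test starts, or during a stable period),

$$\mathrm{SSCI}_1 = \sum_i \frac{m_i - c_i}{c_i}.$$

Dividing by the control removes each subject's own level, which is what
makes the sum meaningful across subjects. The index is additive over
biomarkers, zero at control, and invariant to jointly rescaling a
biomarker's measure and control (`compute_ssci1()`).

During a stress-induction session the index stream can drive a feedback
warning: `warning_trigger()` fires at the earliest sample reaching a
configurable fraction (default 0.8) of a reference maximum. The reference
is taken from a prior calibration session; a running-maximum online mode is
also provided, but since the retrospective rule cannot be evaluated online
it is flagged as a deviation from the calibrated behaviour.

## Temporally coupled, weighted index

Cortisol and glucose have strong time-of-day structure, so the second index
evaluates each measurement against a fitted day-curve baseline $B(t)$ at
its own clock time:

$$\mathrm{SSCI}_2 = \sum_i \omega_i\,
  \frac{m_{i,t} - B_i(t)}{B_i(t)},$$

where the impact weights $\omega_i$ come from ordinary least squares of
STAI-S state-anxiety scores on the relative deviations
(`estimate_weights_mlr()`). Adding the regression intercept puts the
prediction on the STAI-S scale, where 34 and 44 are the critical points
separating Non-AS, Low AS and High AS (`classify_as_state()`).

Two design points were genuinely open and are resolved as follows:

* **Boundary rule.** The cutpoint intervals are left-closed: a score of
  exactly 34 is Low AS and exactly 44 is High AS. Nothing hinges on the
  choice, but it is fixed and tested.
* **Intercept.** The literal index is the intercept-free weighted sum; the
  intercepted sum is what the 34/44 cutpoints apply to, since they live on
  the STAI-S scale. `compute_ssci2()` exposes both.
* **ST inclusion.** Skin temperature shows no response to cold-pressor
  stress (thermoregulation dominates), so the CPT configuration excludes it
  from the weighted sum; other scenarios include it. This is a per-scenario
  flag in `pipeline_config()`.

## Machine-learning chronic-stress index

The chronic stage feeds a 9-element feature vector — retro-adjusted
cortisol and glucose, ST, HR, and five demographic features (gender, age,
height, weight, mean blood pressure) — to five classifiers (random forest,
SVM, Gaussian naive Bayes, gradient-boosted trees, and a one-hidden-layer
neural network with 16 units) and to a linear regression. The
classification target is a four-group depression severity label (ND, DR,
MD, SD); collapsing MD+SD vs ND+DR gives the binary patient/healthy
diagnosis evaluated with ROC and precision-recall curves. The regression
target is the composite severity score itself, and its prediction is the
quantitative index.

Labels come from three scales (SCL-90, SDS, SAS) via
`label_from_scales()`: each scale is min-max normalised to $[0,1]$ and
combined with equal thirds (the original scale-combination weights are not
published; equal weighting after normalisation is the neutral default).
The four-group thresholds default to 0.14 / 0.33 / 0.52, anchored midway
between the group centres the default synthetic design produces; a
composite exactly at a threshold takes the higher class.

# Circadian baseline modelling

## Candidate families and fitting

`fit_baseline()` fits one of five day-curve families over the 08:00-22:00
window by bounded Levenberg-Marquardt nonlinear least squares
(`minpack.lm`), with at most 5000 residual evaluations and box bounds
derived from the data range:

| family | parameters | intended for |
|---|---|---|
| `constant` | level | ST, HR (closed-form mean) |
| `cosinor` | mesor, amplitude, acrophase | cortisol rhythm |
| `harmonic2` | mesor, two amplitude/phase pairs | asymmetric rhythms |
| `skewed_peak` | basal, amplitude, acrophase, concentration, skew | peaked cortisol days |
| `meal_pulse` | basal, amplitude, rise time | glucose with meals |

Initialisation is deterministic — mesor at the data mean, amplitude at half
the data range, acrophase at the argmax time — with no random restarts, so
a fit is a pure function of the data. The acrophase bound is a 24 h window
centred on the argmax, which avoids circular wrap-around without
constraining the solution.

`select_model_loocv()` compares families by leave-one-out cross-validation
with squared-error loss (the loss function is a package choice) and refits
the winner on all points. On rhythmic data the generating family beats the
constant family; on flat data the constant family wins because the rhythmic
families pay a variance penalty. `stl_characterize()` (seasonal-trend
decomposition by loess, via `stats::stl` after linear-interpolation
resampling) is available to inspect the dominant temporal structure before
committing to a family.

ST and HR are not fitted: their day profiles are flat, and their baseline
is the 08:00 measurement, i.e. a constant model.

## Retro-adjustment

`retro_adjust()` maps a value measured at time $t$ to the benchmark time
$t_0$ (default 08:00) **multiplicatively**:

$$v_{\mathrm{adj}} = v \cdot \frac{B(t_0)}{B(t)}.$$

The source method does not state whether the mapping is additive or
multiplicative. The multiplicative rule is adopted because the weighted
index is built on *relative* deviations, and those are exactly invariant
under it:

$$\frac{v_{\mathrm{adj}} - B(t_0)}{B(t_0)} = \frac{v - B(t)}{B(t)}.$$

An additive rule would not preserve this identity. The rule is the identity
at the benchmark and idempotent, both asserted in the tests. A positivity
floor of $10^{-6}$ times the mean baseline level keeps the ratio finite if
a degenerate fit ever drives $B(t)$ towards zero; hitting the floor is an
error, not a silent correction.

# Pulse-waveform heart-rate readout

The raw piezoresistive pulse signal is band-pass filtered and peak-picked:

* **Band 0.5-5 Hz** (default): covers fundamentals from 30 to 200 bpm plus
  low harmonics. The filter is a 2nd-order Butterworth applied
  forward-backward (`signal::filtfilt`), so it is zero-phase and does not
  bias beat times; the input is demeaned first because the DC step
  otherwise excites long edge transients in the backward pass.
* **Peak detection**: local maxima above a height threshold (default 0.4 of
  the series range) with a refractory period (default 0.3 s, capping
  detectable HR at 200 bpm); when two candidates conflict the higher wins,
  and for equal-height plateaus the earliest sample wins.
* **HR**: 60 divided by the *median* inter-beat interval — the median
  rather than the mean so one missed or spurious beat does not move the
  estimate. Fewer than three beats yields a `too_short` flag and a missing
  HR; highly dispersed intervals yield `low_snr`.

The exact published readout algorithm is not available; these parameters
are this package's declared defaults, validated against simulation ground
truth (beat-time accuracy within 20 ms noiseless; HR within 2 bpm at
10 dB SNR across 50-120 bpm).

# What the synthetic generator emulates

`subject_profile()`, `simulate_*()` and `generate_depression_cohort()`
reproduce the statistical structure the analysis relies on:

* **Cortisol**: a single-peak periodic day curve — a von-Mises-style bump
  with an optional monotone phase warp (skew), peaking at the profile's
  acrophase with the trough 12 h away — plus zero-truncated Gaussian noise.
  The default normal-schedule acrophase is **a configuration parameter set
  to 08:00**: the source text and standard physiology disagree on the peak
  time, so no value is hard-coded as truth, and an inverted schedule is an
  exact 12 h circular shift by construction. A coffee habit scales the
  whole curve by 1.25; neither ST nor HR is affected by it.
* **Glucose**: basal level plus one unit-peak gamma-shaped pulse per meal
  (default meals 08:00, 12:30, 18:30; peak 45 min after the meal, then
  exponential-like decay).
* **ST/HR**: stationary around basal values; an exercise habit lowers basal
  HR by 8 bpm.
* **Stress events**: each biomarker is multiplied by
  $1 + \text{intensity}\cdot\text{gain}_b\cdot k(t - \text{onset} -
  \text{lag}_b)$ with a kernel that rises as a half-cosine over the event
  duration to a unit peak and decays exponentially (half-life 20 min
  default). The kernel is exactly zero before onset + lag, so pre-event
  values are conserved bit-for-bit. Default lags put the glucose response
  15 min behind cortisol, matching the delayed glycaemic reaction during
  acute stress. The functional form is a package choice: the reported
  dynamics (rise during the stressor, peak minutes after it ends, recovery
  within about an hour) constrain the shape but not the formula.
* **Pulse waveforms**: three Gaussian bumps per beat — percussion, tidal
  and dicrotic waves with amplitudes 1.0/0.5/0.25, offsets 0/0.22/0.45 and
  widths 0.045/0.07/0.07, all as fractions of the beat period so the
  morphology scales from 30 to 200 bpm — plus white noise at a stated SNR.
  Ground-truth percussion-peak times are stored for validation.
* **Scale scores**: affine maps of a non-negative latent stress level,
  clipped to each scale's admissible range. The STAI-S slope (14 points
  per latent unit above a minimum of 20) anchors latent 1 at the lower
  cutpoint 34, keeping the latent scale interpretable against the
  published critical points.
* **Depression cohort**: 49 subjects (ND 14, DR 12, MD 12, SD 11 — 26 on
  the healthy side, 23 on the patient side), three records each at random
  times in the day window: 147 rows. A per-group latent level scales
  cortisol, glucose and HR multiplicatively and shifts ST, and drives the
  scale scores; subjects share the population day-curve shape scaled per
  subject, so multiplicative retro-adjustment is exact up to noise. The
  default effect sizes are chosen to make the four groups cleanly separable
  (the design the classification stage is specified against);
  `effect_scale = 0` produces a null cohort in which biomarkers carry no
  group signal, used as the leakage guard.

**What it does not emulate**: sensor drift and electrochemical noise,
sweat-rate dynamics, motion artifacts, missing data, realistic
inter-subject correlation of demographics with severity, non-stationary
schedules, or label noise beyond additive Gaussian scale error.
Consequently, a passing test suite shows the *pipeline logic and its
statistical properties* are correct under the stated assumptions — it does
not certify clinical performance numbers, which would require the
(non-public) clinical data.

# Numerical choices

* Noise that must respect positivity is zero-truncated Gaussian, sampled by
  inverse CDF so it is vectorised and bit-reproducible under a seed.
* All stochastic functions take an explicit `seed` and restore the
  caller's RNG state; identical inputs and seed give bit-identical output.
* The train/test split is by **subject**, never by record: with 10 of 49
  subjects held out the split is exactly 117:30 records (about 4:1), and a
  subject-id intersection check runs on every split. Min-max normalisation
  parameters are estimated on the training partition only.
* Feature normalisation of a constant column maps it to zero rather than
  dividing by zero.
* Checks in this package's validation use problem sizes chosen to make the
  statistics sharp but cheap: 100-500 replicate seeds for coverage and
  recovery rates, 30 s pulse traces at 1000 Hz, and the 147-record default
  cohort.

# Known limitations

* Baselines are fit per series (or pooled); there is no mixed-effects
  population model across subjects.
* The LOOCV selector refits every family on every fold — exact but
  quadratic in the number of points; it is intended for the short
  (8-20-point) day series it was designed for.
* Heart-rate variability metrics are deliberately out of scope.
* The five classifiers run with fixed, seeded default hyperparameters;
  there is no tuning stage, so comparisons between algorithms on a given
  cohort reflect those defaults.
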