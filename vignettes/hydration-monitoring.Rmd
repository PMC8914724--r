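---
title: "Estimating time since last drinking from wearable sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time since last drinking from wearable sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling choice

Hydration state is usually assessed invasively (plasma osmolality, urine
characteristics) or by classifying wearable-sensor epochs into
hydrated/dehydrated labels. Labels are the weak point: fasting for a fixed
number of hours does not imply dehydration, and the threshold differs per
person. `hydrowear` instead regresses a continuous, objectively known
target — `sinceLastDrinking`, the elapsed hours between a wearer's last
water intake and each sample — on features from a wrist-worn multi-sensor
unit. The drinking timestamp is cheap to collect, the target is attached
programmatically from timestamps, and an alerting threshold on the
predicted interval can be personalized after the fact.

The sensing model assumes slow autonomic correlates of water deprivation:
the tonic (baseline) skin conductance level drifts as sweat production
changes, and resting heart rate drifts, both over hours — while motion,
respiration and phasic skin-conductance responses vary over seconds. The
pipeline therefore aggregates everything to one-minute means and leaves
fine-grained waveform analysis out of scope.

## The synthetic cohort generator

Real recordings of this kind are scarce, so the package ships a generator
(`sim_config()`, `generate_cohort()`) whose *defaults are the study
conditions* for every test in the package. It emulates:

* **Cohort shape.** Heterogeneous per-subject durations;
  `study_cohort_config()` reproduces the 11-subject design whose durations
  sum to 3386 min (56.4 h). Demographics: height ~ N(159, 7) cm, weight
  regressed on height with positive covariance around 63 kg, age ~ N(30,
  8), gender coded 0/1 with a ~2/11 male share — chosen once to resemble
  a small cohort of desk-working volunteers.
* **Latent dehydration link.** Each subject's hours-since-drinking
  trajectory `h(t)` advances with wall time from a last-drink timestamp
  drawn 1–12 h before recording start. Tonic skin conductance moves by
  `gsr_tonic_slope_per_hour` (default −0.15 µS/h: conductance falls as
  dehydration proceeds; the sign is configurable because the literature
  reports both directions depending on electrode site and climate) and
  heart rate by `hr_slope_per_hour` (default +0.8 bpm/h). `gsr_link =
  "quadratic"` substitutes `h²/6` for `h` — a deliberately non-linear link
  used by the model-comparison tests. No physiologically validated
  dehydration dynamics are claimed; this is a documented synthetic
  stand-in that makes the regression learnable with known structure.
* **Activity.** A two-state rest/active Markov chain sampled per second
  (defaults: P(rest→active) = 0.05, P(active→rest) = 0.10), with
  gyroscope/accelerometer noise variance inflated 20-fold when active —
  wide enough to span resting (~2–5 deg/s) and moving (hundreds of
  deg/s) wrist gyroscope magnitudes.
* **PPG.** Beats at RR intervals around `60000/bpm(t)` ms; RR variability
  is split (fixed, documented) into Gaussian jitter of sd `0.8·rr_sd_ms`
  and a respiratory sinus-arrhythmia sinusoid of amplitude `0.6·rr_sd_ms`
  at `breathing_rate_hz` (default 0.22 Hz), so `rr_sd_ms = 0` yields an
  exactly periodic pulse train and the breathing rate is recoverable from
  the IBI modulation. Each beat is a fixed two-Gaussian template (systolic
  peak at phase 0.25, width 0.11; dicrotic bump at 0.62, width 0.16) —
  the minimal morphology a peak detector needs, with widths that keep the
  fundamental dominant in the spectrum. Motion artifact proportional to a
  zero-mean gyroscope component is added during active seconds.
* **Edge cases by construction.** Per-axis accelerometer readings beyond
  ±16 m/s² with probability `out_of_range_spike_prob` (exercising
  clipping), and conductance x resistance = 1000 (µS x kΩ) exactly at
  every sample. Per-channel summaries of such devices sometimes report
  mean conductance (e.g. 5 µS) alongside a mean resistance (e.g.
  9923 kΩ) that are not mutual reciprocals, because the two channels are
  averaged independently over skewed distributions; the generator
  enforces strict sample-wise reciprocity and matches only the
  conductance scale.

**What it does not emulate:** sweat-electrolyte physiology, device-specific
noise spectra, sensor drop-outs, skin-contact loss, circadian or ambient
confounds, or between-day within-subject variability. Tests passing on
this generator demonstrate that the pipeline recovers structure it was
designed to recover — not that the dehydration link exists at these
magnitudes in real wearers.

The default sample rate is 64 Hz (the hardware default is 512 Hz and is
supported); the analysis consumes one-minute means, so nothing above the
cardiac band is needed, and tests run at 8–32 Hz to keep the suite fast.
A floor of 8 Hz is enforced so the pulse template remains resolvable.

## Preprocessing choices

* **Clipping** is applied only to the accelerometer — the only channel
  with a documented ±16 operating range — in the calibrated stream's
  native m/s² unit. The post-clipping ceiling on |ACC| is
  16·√3 ≈ 27.7 m/s², the magnitude ceiling characteristic of clipped
  recordings from a ±16 m/s² device.
* **Cumulative changes** (`cumulative_change()`) reset to 0 at each
  recording-session start: the quantity represents activity accumulated
  since streaming began, not a lifetime odometer.
* **Minute aggregation** anchors boundaries to the first sample (sessions
  start at arbitrary wall times), takes arithmetic means uniformly —
  including of the cumulative series, which are computed at full rate and
  then minute-averaged like every other channel — and drops the trailing
  partial minute.

## The PPG pipeline

The cleaning chain is: motion classification → adaptive low-pass →
smoothing → beat detection → per-minute features → imputation. Parameters
the user can move, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| motion window | 60 s | aligned with the aggregation grid |
| motion threshold | per-recording median of window means | adapts to each subject's activity mix; ties classify as low |
| low-motion cutoff | 4 Hz | cardiac fundamental ≤ 3 Hz at 180 bpm |
| high-motion cutoff | 2.5 Hz | sacrifices harmonics to suppress broad-band artifact |
| filter family | zero-phase 2nd-order Butterworth (forward–backward) | phase distortion would shift beat instants |
| smoothing window | 0.25 s, rounded odd | removes residual ripple without flattening the systolic peak |
| physiological gate | 40–180 bpm | detections outside it are failures, not errors |

Implementation notes. Both cutoff versions of the filter are computed over
the full reflection-padded signal and the output selects per sample by its
window's state — window boundaries therefore introduce no transients, the
output length always equals the input length, and an all-low recording is
*identical* to a single-pass low-motion filter. Beat detection thresholds
the signal against a 0.75-s moving-average baseline plus half the local
spread, takes one peak per contiguous supra-threshold region, and enforces
a refractory period of 60/180 s keeping the larger of two conflicting
peaks. A flat signal returns a failure flag rather than an exception.

Per minute, at least 3 beats are required; then `ibi` is the mean
inter-beat interval in ms, `bpm = 60000/ibi` exactly, `RMSSD` the root
mean square of successive IBI differences, and the breathing rate the
periodogram peak of the 4-Hz-resampled, detrended IBI series within
0.1–0.5 Hz (at least 8 beats; an amplitude-modulation route would also be
defensible — the IBI route was chosen because the generator encodes
respiration in RR, and both place the default 0.22 Hz inside the band).
Failed minutes inherit the previous successful minute's four values; a
failure before any success takes documented cold-start defaults (bpm 78,
ibi 772 ms, breathing rate 0.22 Hz, RMSSD 75.2 ms — cohort-scale means)
and logs a message. Note the cold-start pair deliberately keeps the
published means and therefore does not satisfy `bpm·ibi = 60000`; that
identity is guaranteed only where `success = TRUE`.

## Feature sets and diagnostics

FEAT1 is the 19-column set: the PPG mean, the four beat features, both GSR
channels, the three magnitudes and three cumulative sums, temperature,
pressure, and the broadcast personal features (age, height, weight, gender
coded 0 female / 1 male — a numeric coding is required for VIF and is the
package's documented, configurable choice). FEAT2 prunes it to 12: BMI
replaces height and weight, one combined motion ratio
(`cumAccel/Accel_mag + cumMag/Mag_mag + cumGyro/Gyro_mag`, computed
per minute-row) replaces the six kinematic columns, and `ibi` is dropped
as linearly tied to `bpm`.

`vif()` regresses each feature on all others by OLS with intercept and
reports `1/(1 − R²)`; exact collinearity is flagged `Inf` and constant
columns `NA` (never silently dropped). VIFs are computed on the encoded
feature columns only, without the target; no claim is made that synthetic
VIFs match any published real-data values. `feature_importance()` returns
impurity-reduction importances of a 100-tree random forest, normalized to
sum to one.

## Evaluation protocols

`run_comparison()` repeats, `n_runs = 10` times by default: shuffle rows,
hold out 30% (row-wise random — the subject-held-out structure belongs to
the transfer protocol only), fit every learner, score MAE and RMSE in
hours. Hyperparameters are pinned ecosystem defaults: 100 trees for the
forests, 100 boosting stages of depth 3 at learning rate 0.1, RBF-kernel
SVR at cost 1, penalized linear models with a cross-validated penalty on
deterministic folds. The "ANN" is a zero-hidden-layer, linear-activation
network; the "DNN" is a single-hidden-layer perceptron (16 units, weight
decay 1e-3, 200 epochs) — a deeper multi-layer stack was considered, but
the single-hidden-layer form supports exact warm-starting from stored
weights, which the transfer protocol requires, and already separates the
non-linear from the linear learners on the test cohorts. Model size is the
byte length of the learner's canonical serialization and training time is
wall-clock around the fit; both are reported but never asserted, being
platform-dependent.

`transfer_eval()` implements leave-one-subject-out personalization: fit a
base model on all other subjects, personalize with a random `1 − f` share
of the held-out subject's rows, test on the remaining `f ∈ {0.3, 0.7}`.
Network learners continue training from the base weights; tree and other
re-fittable learners are re-fitted on the pooled base + personalization
rows (a subset-only re-fit is available via `pooled = FALSE` — pooling was
chosen because a forest re-fitted on a few dozen rows alone discards the
cohort prior). Subjects with fewer than 10 rows are skipped with a
warning. The generator's per-subject tonic-conductance offsets
(`subject_gsr_sd`) are exactly the bias a base model cannot know and
personalization can absorb.

On the package's fixed-seed non-linear test cohort the four non-linear
learners (forests, boosting, DNN) occupy the lowest error slots, strictly
below every linear model and the baseline, and this ordering — not a full
ranking — is what the regression tests assert: a depth-3 gradient-boosted
ensemble is competitive with the forests on smooth synthetic links, so any
finer ordering among the non-linear learners is fixture-dependent and is
deliberately not asserted.

## Problem sizes and numerical conventions

Test cohorts use 3–6 subjects with 10–25-minute recordings at 16–32 Hz
(the duration-accounting check generates the full 3386-minute design at
8 Hz); the comparison suite runs 3 splits and the acceptance script 10.
Degenerate inputs are contracts, not crashes: an all-probability-zero,
zero-noise configuration is legal and exactly periodic; recordings under
two minutes are rejected at aggregation; empty series, even smoothing
windows, inverted cutoffs and negative drink intervals raise errors naming
the violated condition; flat PPG yields `success = FALSE`.

## Known limitations

The dehydration link is synthetic and linear (or quadratic) by
construction; nothing here validates the physiological magnitudes. The
within-subject target range in short recordings is narrow, so row-wise
splits flatter memorizing learners — mirroring the real difficulty that
motivates the transfer protocol. Breathing-rate estimation needs ≥ 8
beats per minute window and degrades at high motion. Model size on disk is
a proxy; in-memory embedded footprints require device benchmarking outside
this package's scope, as do quantization, federated training and
power-consumption measurement.
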