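---
title: "Belt-worn inertial sensing: signal derivation, activity recognition, posture and waistline estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belt-worn inertial sensing: signal derivation, activity recognition, posture and waistline estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`beltsense` implements the analysis stack of a belt-buckle wearable: a
tri-axial accelerometer and gyroscope drive daily-activity recognition and
sitting-posture assessment, and a buckle magnetometer watching a pivoting
blade ride a sawtooth-machined belt surface measures how far the belt is
inserted — hence the wearer's waistline. This vignette is the package's
account of the methods: the processing chain, the conventions that had to
be frozen for reproducibility, the choices made where the design was
genuinely open, and what the synthetic test substrate does and does not
demonstrate.

The axis convention is fixed rather than inferred from hardware: with the
wearer upright, X points up the trunk, Y is lateral, Z anterior.
Acceleration is kept in gravitational units (g) and angular velocity in
rad/s end to end; unit conversion belongs at the I/O boundary. The default
sampling rate is 100 Hz, so the 128-sample analysis window spans 1.28 s.

## Signal derivation (17 channels)

`derive_signals()` runs the pre-processing chain per axis:

1. **Denoising** — width-3 median filter (one-sample spikes vanish, wider
   waveforms are undistorted), then a third-order Butterworth low-pass at
   20 Hz. All filtering is zero-phase (forward–backward) so no group delay
   shifts signal content relative to window boundaries; this is an offline
   pipeline, so the acausal pass is free. The forward–backward pass runs
   on an odd-reflection-padded copy spanning about six filter time
   constants, which keeps edge transients out of the data and passes
   constants through exactly.
2. **Gravity/body separation** — a 0.3 Hz third-order zero-phase
   Butterworth low-pass estimates gravity; body motion is defined as the
   difference, so the two components reconstruct the denoised signal to
   machine precision by construction. The 0.3 Hz time constant is ~3 s:
   recordings much shorter than ~10 s sit inside the filter transient and
   are rejected below 12 samples outright.
3. **Differentiation** — jerk (of body acceleration) and angular
   acceleration (of angular speed) use central differences in the
   interior and one-sided differences at the two ends, keeping every
   channel the same length and sample-aligned.
4. **Magnitudes** — per-sample Euclidean norms of each tri-axial signal.
5. **Frequency channels** — the body-acceleration, body-jerk and
   angular-speed tri-axial signals plus the four body magnitude signals
   get a per-window FFT. The gravity channels (no motion content above
   0.3 Hz by construction) and the tri-axial angular acceleration stay
   time-domain only, giving 10 time + 7 frequency = 17 channels.

Whether the FFT is applied per window or to the full stream is a genuine
open point; per window is standard practice in windowed activity
recognition and is what the feature functions consume, so the frequency
channels are stored per window. The frozen FFT convention is the one-sided
magnitude spectrum, `Mod(fft(x))[1:(N/2+1)] / N` — 65 bins from DC to
Nyquist at 0.78125 Hz spacing for the default window — with no taper.
Normalising by window length makes energy features scale-stable across
window sizes.

## The 561-feature enumeration

The feature vector applies the classical windowed statistics (mean, std,
mad, max, min, energy, sma, entropy, iqr, Burg autoregression,
correlation, angle; for spectra also maxInds, meanFreq, skewness,
kurtosis, band energies) across the 17 channels in the enumeration that
is standard for 561-feature inertial HAR:

| block | per signal | signals | total |
|---|---|---|---|
| tri-axial time stats + AR(4)×3 + 3 correlations | 40 | 5 | 200 |
| magnitude time stats + AR(4) | 13 | 5 | 65 |
| tri-axial spectrum stats + 42 band energies | 79 | 3 | 237 |
| magnitude spectrum stats | 13 | 4 | 52 |
| angles to the gravity vector | — | — | 7 |

Band energies use 14 fixed bands of the 64 non-DC bins (eight 8-bin, four
16-bin, two 24-bin bands) per axis. The angle features measure the angle
between each window-mean body vector (acceleration, jerk, angular speed,
angular acceleration) or unit axis and the window-mean gravity vector.
`feature_names()` publishes the full frozen order; it is stable across
runs and serialisation.

Conventions that the printed formulas leave open were fixed once:

* **std, skewness, kurtosis** use population (1/N) moments; kurtosis is
  the raw ratio, not excess. Zero-variance windows return 0 for the shape
  statistics so vectors stay finite.
* **sma** is computed with an additional 1/N over the printed channel-sum
  so the value is window-length invariant — standardization would absorb
  the constant anyway, but invariance keeps the feature meaningful across
  window configurations.
* **entropy** is Shannon entropy (natural log) of the window's absolute
  values normalised to weights, with 0·log 0 = 0 and an all-zero window
  defined as 0. The printed sum of `c_i log c_i` over signed weights is
  not a well-defined entropy; the negated absolute-value form is.
* **iqr** uses the linear-interpolation quantile (type 7).
* **correlation** of a (near-)constant channel is defined as 0 rather
  than NaN, keeping static windows finite.
* **Burg AR(4)** is fit without mean removal (the plain recursion);
  degenerate windows yield four zeros.
* **energyBand**'s printed prefactor `1/(a−b+1)` is negative for any real
  band; it is implemented as the evident `1/(b−a+1)` mean of squares.
* **maxInds / meanFreq** operate on the 65-bin one-sided spectrum with
  1-based bin indices.

`range()` and `rms()` are implemented and exported with the other feature
functions but are not part of the frozen 561 enumeration, which follows
the established convention exactly.

Windows are 128 samples at 50 % overlap, enumerated from offset 0 with a
64-sample step; a trailing partial window is dropped. Window labels are
the majority per-sample label, ties broken by the earliest label, and
windows mixing more than two labels can be dropped (`drop_mixed`) to
exclude activity transitions.

Standardization is per-feature location/scale (mean, sample sd) estimated
on training windows only and then frozen — held-out data is transformed
with the training parameters, never refit, so evaluation has no
information leakage. Degenerate features fall back to scale 1 (flagged)
and standardize to 0.

## Activity recognition

The recogniser is a random forest over the 7 classes (lay down, sit,
stand, walk, walk down/up stairs, run). Forest hyperparameters are the
library-standard baseline — 100 trees, unlimited depth, `floor(sqrt(561))
= 23` candidate features per split — with a fixed seed recorded in the
model metadata; fits and predictions run single-threaded so results are
bit-reproducible.

Two evaluation schemes are provided. Stratified 10-fold cross-validation
shuffles windows (seeded) and assigns them per class round-robin, so fold
sizes per class differ by at most one; windows from one recording can
land in both train and test folds, which measures within-corpus accuracy.
Leave-one-person-out holds out each subject in turn and measures
cross-subject generalisation; per-subject and per-group (e.g. by gender)
reports are available. Splitting is window-level by design; callers who
want session-level splitting can evaluate with subject ids per session.
F1 is reported both support-weighted and macro, alongside the pooled
confusion matrix.

## Posture monitoring

Attitude angles come from the gravity direction:
θ = atan(AccX/√(AccY²+AccZ²)), ψ = atan(AccY/√(AccX²+AccZ²)),
ϕ = atan(√(AccX²+AccY²)/|AccZ|), in degrees. The ϕ denominator is taken
as |AccZ| (a ratio of magnitudes), which puts the axis-aligned cases at
exactly 0°/90° and makes ϕ ∈ [0°, 90°]; ϕ = 90° when AccZ = 0. The
angles are scale-invariant, so no 1 g normalisation is needed.

A good sitting posture satisfies two policies: lateral tilt near
horizontal (|ψ| within a tolerance of 0°) and front-rear tilt near
vertical (ϕ within a band). The published targets — ψ ≃ 0, ϕ in 80–90° —
come without exact cutoffs, so the rule object defaults to ±10° for ψ and
[80°, 90°] for ϕ, all configurable; whether the deployed policy used
sharp cutoffs or hysteresis is unknowable from the description, and an
explicit tunable rule is the honest encoding. `monitor_posture()`
computes the angles on the 0.3 Hz gravity component rather than raw
acceleration so transient motion does not flip the assessment — an
assumption, recorded here.

Session statistics are the poor-posture rate (fraction of assessed time
poor) and the improvement rate between an intervention-off and an
intervention-on block, `100 · (r_off − r_on)/r_off`.

## Intervention engine

A pure, deterministic state machine: posture monitoring is active only
while the recognised activity is *sit*; poor posture sustained past a
debounce (default 5 s) fires one belt vibration; continuous sitting/lying
past a sedentary limit (default 30 min) fires a walk-prompt notification.
Each cause has a refractory spacing (default 60 s), the streak clock
restarts on firing, and leaving the triggering state resets it. All
timing constants are unstated in the source system and therefore exposed
in `engine_config()` with the defaults above. Event counts are monotone
non-increasing in every timing parameter, and replaying the same input
reproduces the identical event log. The radio/app transport is abstracted
to an event data frame (`t, channel, cause, pattern`); vibration patterns
are opaque identifiers.

## Waistline estimation

Each 0.6 cm sawtooth tooth drives one blade oscillation, so insertion
distance is (cycle count) × pitch and the waistline is belt length minus
insertion minus a per-belt calibration offset that absorbs the buckle
geometry. The pitch is "around 0.6 cm" physically and is a configurable
calibration parameter.

The cycle counter is a Schmitt trigger on the lightly smoothed, linearly
detrended trace rescaled to its robust (1–99 %) amplitude range: a count
requires crossing above 60 % of the range after having been below 40 %.
Relative thresholds make the count invariant to amplitude scaling and to
baseline drift; noise smaller than the 20 % hysteresis band cannot
double-count. A flat trace has no range and counts zero. A scalar count
cannot distinguish insertion from removal, so the estimator addresses a
single monotone insertion event; session segmentation is the caller's
responsibility — a recorded limitation.

The quantisation geometry sets the accuracy floor: a mid-tooth truth can
be off by up to one pitch (0.6 cm), and over uniformly random depths the
mean absolute error of the 0.6 cm grid is at most 0.3 cm. These bounds —
not any hardware error figure, which depends on physical blade and magnet
noise that a synthetic trace cannot represent — are what the tests and
the acceptance script verify.

## Synthetic data: what it shows and what it cannot

The generators replace an undeposited human-subjects corpus, so their
defaults define the package's study conditions: 17 synthetic subjects,
16 s per activity per subject (24 windows per class per subject at
100 Hz — sizes chosen so the full evaluation runs in minutes on one
core), heterogeneity scale 1.

Activity kinematics are deliberately stylised: a gravity orientation per
posture (upright X; supine Z; sitting reclined 12° toward Z) plus
sinusoids at characteristic cadences (walk 1.8 Hz, stairs 1.5 Hz with
up/down amplitude asymmetry and landing-impact harmonics down, run
2.8 Hz) and Gaussian noise, all configurable. Subjects differ by an
amplitude gain (±25 %), cadence factor (±10 %), a fixed buckle tilt
(σ = 6° pitch, 4° yaw) and a noise scale. Everything is seeded: the same
seed reproduces recordings bit-exactly, and changing the seed changes
only noise and phase realisations, never the class structure. One
consequence of the construction worth knowing: the *magnitude* of an
oscillating body-acceleration signal is rectified, so its spectrum peaks
at twice the cadence; cadence checks belong on the per-axis spectra.

Because class means are separable by construction, a high 10-fold F1 on
this substrate demonstrates that the pipeline — filters, features,
standardization, folds, forest — is wired correctly, not that real
activities are this easy. The qualitative cross-subject effect is
reproduced (10-fold F1 exceeds leave-one-person-out F1 under subject
heterogeneity, and shuffled labels score at the 1/7 chance level), but
the quantitative gap is smaller than on real humans, whose individual
differences are far richer than four multipliers. Likewise the
magnetometer generator renders an idealised sawtooth; it validates the
counting algorithm's resolution bound, not hardware accuracy. None of
the generators model soft-tissue artifacts, sensor bias, or gait
variability.

## Numerical and degenerate-input policy

Filters reject non-finite samples and recordings shorter than the filter
warm-up (12 samples); sampling below twice the 20 Hz cutoff is rejected
by the Nyquist guard. The FFT requires power-of-two windows. Feature
extraction fails loudly, naming the offending feature, if any value goes
non-finite. Free-fall (zero acceleration) makes attitude undefined and is
rejected. Estimator ties are broken deterministically (earliest label;
`which.max`'s first maximum), and every stochastic step takes an explicit
seed, so the whole pipeline is replay-identical.
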