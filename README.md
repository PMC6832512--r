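# beltsense

Analysis toolkit for a belt-buckle wearable that monitors health behaviour:
a tri-axial accelerometer + gyroscope at the buckle recognises daily
activities and assesses sitting posture, and a magnetometer watching a
pivoting blade ride the belt's sawtooth-machined back surface measures how
far the belt is inserted — and therefore the wearer's waistline. The
package is aimed at researchers in wearable sensing and digital health who
want the full pipeline as tested, scriptable building blocks, with
seedable synthetic generators standing in for the belt hardware.

## What it implements

**Signal derivation.** Raw 100 Hz streams are denoised (width-3 median +
20 Hz third-order zero-phase Butterworth), acceleration is split into
gravity and body motion at 0.3 Hz, jerk and angular acceleration are
derived, magnitudes taken, and seven channels mapped to the frequency
domain per 128-sample window — 17 named channels (10 time, 7 frequency).

**Feature extraction.** 50 %-overlapping 1.28 s windows yield a frozen
561-element feature vector (`feature_names()` publishes the order):
windowed statistics, signal magnitude area, entropy, interquartile range,
order-4 Burg autoregression, inter-axis correlations, spectral statistics,
14-band spectral energies, and angles to the gravity vector — plus
train-only standardization with frozen parameters for held-out data.

**Activity recognition.** A seeded random forest (100 trees, √p features
per split) over the 7 classes — lay down, sit, stand, walk, walk
down/up stairs, run — with stratified 10-fold cross-validation,
leave-one-person-out evaluation, confusion matrices and weighted/macro F1.

**Posture monitoring.** Attitude angles from the gravity direction,

    θ = atan(AccX / √(AccY² + AccZ²)),  ψ = atan(AccY / √(AccX² + AccZ²)),
    ϕ = atan(√(AccX² + AccY²) / |AccZ|)

with the two-policy good-sitting rule (|ψ| ≤ 10°, ϕ ∈ [80°, 90°],
configurable), poor-posture rates per session and improvement rates
between intervention-off and intervention-on blocks.

**Intervention engine.** A deterministic state machine: posture monitoring
activates while sitting; sustained poor posture fires a belt vibration
after a debounce, prolonged sitting/lying fires a walk prompt, each cause
with its own refractory period.

**Waistline estimation.** Schmitt-trigger cycle counting on the
magnetometer trace (relative hysteresis thresholds, drift-tolerant),
insertion = count × 0.6 cm tooth pitch, waistline = belt length −
insertion − calibration offset.

**Synthetic data.** Seeded generators for labelled multi-subject IMU
recordings of the 7 activities (stylised kinematics with per-subject
heterogeneity) and sawtooth magnetometer insertion traces — the test
substrate for everything above.

## Worked example

```r
library(beltsense)

rec <- generate_activity("walk", duration = 8, seed = 42)
rec
#> <imu_recording> 800 samples @ 100 Hz (8.00 s)
#>   labels: walk=800

sig <- derive_signals(rec)
sig
#> <belt_signals> 800 samples @ 100 Hz, 11 windows of 128 samples
#>   channels: 10 time + 7 frequency

fw <- extract_features(sig, 0)   # first 1.28 s window
round(fw$features[c("tBodyAcc-mean()-X", "tBodyAcc-std()-X",
                    "fBodyAcc-maxInds-X", "tGravityAccMag-mean()")], 4)
#>     tBodyAcc-mean()-X      tBodyAcc-std()-X    fBodyAcc-maxInds-X
#>                0.0791                0.2089                3.0000
#> tGravityAccMag-mean()
#>                0.9368
```

The body-acceleration X channel oscillates with ~0.21 g spread around a
near-zero mean — gait, not gravity; the spectral maximum at bin 3
(bins are 0.78 Hz wide, DC = bin 1) sits at the 1.8 Hz walking cadence;
and the gravity magnitude stays at ~1 g. A waistline measurement from a
synthetic insertion trace, and a posture check:

```r
est <- estimate_waistline(generate_mag_trace(23.5),
                          belt_config(belt_length_cm = 110, offset_cm = 4),
                          truth_cm = 23.5)
est
#> <waistline_estimate> 39 cycles -> insertion 23.4 cm, waistline 82.6 cm
#>   vs truth: absolute error 0.10 cm (0.4%)

a <- attitude_angles(c(0.97, 0.05, 0.24))
a
#> <posture_angles> theta 75.8 deg, psi 2.9 deg, phi 76.1 deg
assess_posture(a)
#> [1] "poor"        # phi below the 80-90 degree vertical band: slouched

improvement_rate(0.5, 0.076)
#> [1] 84.8          # percent reduction of poor-posture time
```

39 counted blade cycles × 0.6 cm pitch quantise 23.5 cm to 23.4 cm —
within one tooth of the truth, which is the method's resolution.

A command-line interface wrapping the same functions is installed as
`exec/beltsense` (`simulate`, `extract`, `evaluate`, `posture`,
`waistline`, `intervene`).

See `vignette("belt-activity-pipeline")` for the methods account: every
frozen convention (FFT, feature formulas, enumeration), the open design
points and how they were decided, and what the synthetic substrate does
and does not demonstrate.

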