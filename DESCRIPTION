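Package: beltsense
Title: Belt-Worn Inertial Sensing for Activity Recognition, Posture
    Monitoring, and Waistline Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and modelling toolkit for a belt-buckle
    inertial measurement unit (tri-axial accelerometer and gyroscope) plus a
    buckle magnetometer. Implements the standard human-activity-recognition
    pipeline: median/Butterworth denoising, gravity/body separation, jerk and
    magnitude signal derivation (17 named channels), 50 percent overlapping
    128-sample windowing with a frozen 561-element feature enumeration,
    random-forest recognition of seven daily activities with stratified
    k-fold and leave-one-person-out evaluation, accelerometer attitude-angle
    sitting-posture assessment with a configurable good-posture policy and a
    vibrotactile intervention state machine, and sawtooth-pitch magnetometer
    peak counting for belt insertion distance and waistline estimation.
    Includes seedable synthetic generators for labelled belt-worn recordings
    and magnetometer insertion traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
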