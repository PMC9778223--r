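Package: kneemon
Title: Knee-Extension Rehabilitation Monitoring from Surface EMG and
    Accelerometer-Derived Range of Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and session-evaluation pipeline for
    knee-extension rehabilitation monitoring. Conditions two-channel
    surface electromyography (vastus lateralis and vastus medialis)
    with a high-pass/low-pass/power-line-notch digital filter bank,
    extracts windowed mean-absolute-value (MAV) and root-mean-square
    (RMS) amplitude features, estimates the knee-extension angle and
    range of motion (ROM) from accelerometer tilt, segments exercise
    repetitions with a hysteresis detector, runs a threshold-based
    rehabilitation session engine with binary pass/fail feedback, and
    aggregates per-subject and per-group summaries for progress
    tracking. Includes a seeded simulator of coupled knee-angle and
    EMG recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
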