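Package: activital
Title: Activity-Aware Vital-Sign Monitoring from Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes multi-sensor wearable recordings (triaxial
    accelerometers on the chest, wrist and ankle plus a single-lead ECG)
    into activity-conditional vital-sign surveillance. Extracts heart rate
    from ECG R peaks and breathing rate from the ECG-derived respiration
    (EDR) tachogram, recognizes eight activities of daily living with a
    two-layer intensity-gated sensor-fusion classifier, learns per-activity
    green/yellow/red vital-sign zones by a five-bin histogram procedure,
    and emits graded warnings and alerts when measurements leave the normal
    zone. Includes a synthetic-data generator with known ground truth so
    the full pipeline is testable without any external dataset, and an
    optional reproduction mode for the public MHEALTH recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    rpart,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
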