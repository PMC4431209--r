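Package: vitalsentry
Title: Prediction-Based Sensor-Anomaly Detection for Multivariate Vital-Sign Streams
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes true medical alarms from sensor-fault false alarms in
    multivariate physiological monitoring streams (arterial blood pressure, heart
    rate, pulse, respiration, oxygen saturation). Each parameter is forecast one
    step ahead from a sliding window of recent values by epsilon-insensitive
    support-vector regression; the absolute forecast error is compared against a
    dynamic threshold equal to a multiple of the sliding-window standard
    deviation, and per-parameter anomaly flags are combined by majority voting:
    a strict majority of flagged parameters indicates a correlated physiological
    change (true alarm), a minority indicates an uncorrelated sensor fault
    (false alarm). Includes a seeded synthetic vital-sign generator with
    injectable correlated medical events and single-sensor faults, CSV I/O for
    MIMIC-numerics-style records, a predictor comparison harness, and a
    detection-rate / false-positive-rate / ROC evaluation layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    kernlab,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'series-io.R'
    'generate.R'
    'prediction.R'
    'detection.R'
    'evaluation.R'
    'pipeline.R'
    'cli.R'
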