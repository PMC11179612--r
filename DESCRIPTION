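Package: cadenza
Title: Dynamic Cerebral Autoregulation and Neurovascular Coupling
    Analysis During Cognitive Task Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for beat-to-beat cerebral haemodynamic
    recordings during cognitive paradigms: artefact removal and beat-averaged
    5 Hz resampling of arterial blood pressure, transcranial Doppler blood
    velocity, ECG and end-tidal CO2 signals; short-segment Welch transfer
    function analysis between mean arterial pressure and cerebral blood
    velocity; estimation of the Tiecks Autoregulation Index (ARI) by template
    fitting of the blood-velocity step response with coherence and
    normalised-mean-square-error acceptance gates; objective
    responder/non-responder classification of neurovascular coupling
    responses via cross-correlation peak and variance-ratio criteria with
    null-calibrated thresholds; visit-to-visit reproducibility statistics
    (intraclass correlation, within-subject coefficient of variation); and a
    seeded synthetic-recording generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
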