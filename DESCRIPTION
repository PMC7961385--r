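Package: hemoradar
Title: Classification of Hemodynamic Scenarios from Continuous-Wave Radar and
    Contact Vital-Sign Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying five hemodynamic scenarios
    (resting, Valsalva maneuver, simulated apnea, tilt up, tilt down) from
    continuous-wave Doppler radar and synchronized contact reference signals.
    Provides a synthetic multi-channel cohort generator with known ground
    truth, radar I/Q ellipse reconstruction and arctangent demodulation,
    derivation of cardiorespiratory signals (distance, respiration, heart
    sound, pulse), unified resampling and Butterworth band-pass filtering,
    overlapping-window segmentation with button-press based labeling, SMOTE
    class balancing, branched multi-input fully-connected neural networks
    trained by minibatch gradient descent, and a subject-blocked stratified
    5-fold cross-validation harness with normalized confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
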