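Package: mgsaccade
Title: Memory-Guided Saccade Task Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for memory-guided saccade task (MGST) eye-tracking data:
    display geometry and pixel/visual-angle conversion, randomised trial
    scheduling, a synthetic 250 Hz binocular gaze generator with per-trial
    ground truth, recording preprocessing (gap-fill interpolation, eye
    averaging, windowed angular velocity), velocity-threshold (I-VT) event
    detection with fixation merging and minimum-duration filtering, trial
    validity gating with an early/late error taxonomy, saccade metric
    extraction (latency, amplitude, duration, mean and peak velocity, time
    to peak, gain), per-subject aggregation, and a statistical layer with
    Spearman/Pearson correlations against neuropsychological covariates and
    a late-error-rate multiple regression with assumption diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lmtest,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
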