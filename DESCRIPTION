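Package: jumpload
Title: Accelerometry-Based Prediction of Mechanical Loading During Jumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate skeletal mechanical loading from body-worn
    accelerometers during high-impact jumping exercise. Implements the raw
    signal processing chain (resampling, zero-phase Butterworth low-pass
    filtering, resultant-vector computation, cross-correlation clock
    synchronization), impact-event extraction (peak detection with a
    mean-plus-3-SD threshold and minimum-separation rule, force-peak matching,
    centered-derivative loading rates), a registry of twelve published
    regression equations predicting peak ground reaction force and peak
    loading rate from peak acceleration, peak acceleration rate and body mass
    at three sensor placements, and the validation machinery around them:
    linear mixed models with subject and jump-condition random intercepts,
    conditional R-squared, subject-wise leave-one-out cross-validation,
    MAE/MAPE/RMSE accuracy indices and Bland-Altman agreement analysis. A
    synthetic paired force-plate/accelerometer jump simulator with known
    ground truth makes the whole pipeline testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    lme4,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
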