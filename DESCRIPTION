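Package: ahepredict
Title: Patient-Specific Prediction of Acute Hypotensive Episodes from
    Per-Minute Vital Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting patient-specific acute hypotensive
    episodes (AHE) from per-minute bedside-monitor vital signs (mean
    arterial pressure, heart rate, SpO2).  Implements a relative,
    moving-average based AHE definition and annotator alongside the
    conventional fixed-threshold definition; observation-window/gap-length
    sample extraction with independence and quality rules; windowed
    preprocessing (physiological-range filtering, back/forward-fill
    imputation, static-range normalisation); recurrent classifiers (a
    stacked LSTM and a missing-data-tolerant gated unit with trainable
    exponential decay) together with mean-feature logistic-regression and
    SVM baselines; transfer-learning fine-tuning; and bootstrap-evaluated
    discrimination metrics.  A synthetic vital-signs cohort generator with
    plantable events, precursor signals, missingness and artifacts supports
    development and validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
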