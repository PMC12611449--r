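Package: spescast
Title: Seizure Forecasting from Intracranial EEG Responses to Paired-Pulse
    Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for stimulation-based seizure forecasting
    from intracranial EEG. Generates seeded synthetic cohorts with paired
    single-pulse electrical stimulation, stimulus artifacts, evoked
    responses and a pre-ictal rise in background variance and lag-1
    autocorrelation (critical slowing down); preprocesses recordings
    (common-average reference, anti-aliased downsampling to 256 Hz,
    cubic-spline artifact repair, zero-phase Butterworth filtering);
    extracts window-relative variance/autocorrelation features with
    trailing cumulative averages; fits a leave-one-patient-out logistic
    forecaster; and evaluates it with a threshold/seizure-occurrence-period
    alarm system via sensitivity, time in warning, improvement over chance,
    Brier Skill Score and shuffled-forecast chance levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
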