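Package: sepseval
Title: Evaluation of Streaming Sepsis Risk Scores Against Computable Sepsis Definitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for silent-deployment evaluation of a streaming in-hospital
    sepsis risk score against three electronically computable sepsis
    definitions (Sepsis-3, a SEP-1-based severe-sepsis definition, and the
    CDC Adult Sepsis Event). Provides per-encounter time-zero phenotyping
    with criterion-level provenance, encounter- and prediction-level
    evaluation instances, lead-time and pre-treatment censoring analyses,
    discrimination, calibration and decision-curve metrics, operating-point
    selection with number-needed-to-evaluate, patient-clustered bootstrap
    confidence intervals, weekly drift tables, and a synthetic EHR
    event-stream generator with planted, exactly recoverable case truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
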