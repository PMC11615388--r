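Package: edfuse
Title: Event-Driven Multimodal Risk Prediction for Emergency Department Deterioration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting clinical deterioration of emergency department
    patients from irregular multimodal event streams. Admissions are converted
    into per-event prediction windows with 12-horizon binary labels; each window
    is embedded as a variable-length token set (one token per observation, the
    sum of a time embedding, a value embedding and a feature/modality embedding,
    with no imputation of unobserved features) and fused by a small transformer
    encoder feeding a 12-horizon sigmoid classifier head. Includes a per-horizon
    logistic-regression baseline with carry-forward and mean-fill imputation,
    per-horizon and macro-averaged evaluation metrics, post hoc feature-ablation
    importance, input-sequence-length and dense-vitals time-resolution analyses,
    and a synthetic emergency-department cohort simulator with a planted hazard
    so the whole pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    pROC
Config/testthat/edition: 3
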