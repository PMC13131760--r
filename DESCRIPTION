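Package: qvcv
Title: Consonant-Confusion Testing for Predicting Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a quick closed-set consonant-confusion speech-in-noise
    test: stimulus-panel optimization (SNR90 normalization of per-token
    psychometric functions, ROC/AUC-based token screening), prediction of the
    pure-tone-average (PTA) hearing threshold from vectorized consonant
    confusion matrices via PCA and ridge-penalized regression with repeated
    cross-validation, piecewise audibility baselines and residual-loss
    ("excess loss") detection, test-retest repeatability curves, and
    hearing-aid benefit quantification. Includes a seeded synthetic-listener
    simulator so every analysis is exercisable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
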