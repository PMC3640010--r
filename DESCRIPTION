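Package: episelect
Title: Outcome Prediction for Temporal Lobe Epilepsy Surgery from
    Categorical Clinical and Neuropsychological Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for predicting the post-surgical outcome
    (Engel class, dichotomised as seizure-free versus improvement-only) of
    temporal lobe epilepsy patients from categorical clinical and
    neuropsychological features. Provides a validated categorical cohort data
    model with class-conditional mode imputation; three supervised paradigms
    (categorical naive Bayes, ridge-penalised logistic regression and Hamming
    k-nearest-neighbour) evaluated by leave-one-out cross-validation with
    accuracy, AUC and F-measure; a bootstrap race-search feature-selection
    ensemble with selection-frequency ranking and incremental subset curves;
    exact tie-aware Wilcoxon rank-sum and signed-rank tests on ordinal
    categories; a two-component multinomial-mixture EM clustering with soft
    responsibilities and outcome-agreement scoring; and a synthetic cohort
    generator with planted class-dependent features for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
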