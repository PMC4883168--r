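Package: oatlmt
Title: Epileptic Seizure Detection from EEG via Optimum-Allocation Sampling
    and Logistic Model Trees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects epileptic seizure activity in multichannel EEG
    recordings. Each class recording is segmented in time, a representative
    sample of time points is drawn by optimum-allocation stratified sampling
    (allocation proportional to within-segment variability), eleven
    descriptive statistics are extracted per channel from the combined
    sample, and the resulting feature matrix is classified with a logistic
    model tree (LogitBoost with simple linear base learners, grown and
    pruned by internal cross-validation), ridge-penalised multinomial
    logistic regression, or a support vector machine. Performance is
    assessed by repeated stratified k-fold cross-validation with per-class
    sensitivity, specificity, precision, F-measure and ROC area, overall
    accuracy, Cohen's kappa and the mean absolute error of the probability
    estimates. A synthetic benchmark-shaped EEG generator makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
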