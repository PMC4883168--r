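# oatlmt

Detection of epileptic seizure activity in multichannel EEG from
descriptive statistics of an **optimum-allocation sample**, classified
with a **logistic model tree**.

Scalp EEG separates into three diagnostic states — healthy, seizure-free
(interictal) and seizure (ictal) — but class recordings are large and
non-stationary. Rather than featurising every time point, `oatlmt`
segments each class recording into `k` contiguous parts, determines the
class's total sample size from the classical proportion-estimation
formulas

    n0 = z² p (1 − p) / d²,        n = n0 / (1 + (n0 − 1) / N),

and allocates `n` across segments proportionally to
`N_i · sqrt(Σ_j S_ij²)` — the segment length times the root of its summed
per-channel variances — so the most variable stretches of signal
contribute the most rows. The pooled sample of each class is reduced to
eleven statistics per channel (mean, median, mode, SD, Q1, Q3, IQR,
skewness, kurtosis, min, max), and the channels-by-features matrix is
classified with one of:

* **LMT** — logistic model tree: a decision tree whose nodes carry
  additive logistic models built by LogitBoost with single-feature
  linear base learners, grown with warm-started child committees and
  pruned by cost-complexity pruning with internal cross-validation
  (implemented in this package);
* **MLR** — multinomial logistic regression with a ridge estimator
  (implemented in this package);
* **SVM** — a thin adapter over libsvm (`e1071`), RBF kernel, one-vs-one.

Performance is assessed by stratified 10-fold cross-validation repeated
20 times: per-class sensitivity, specificity, precision, F-measure and
ROC area, overall accuracy, Cohen's kappa and the mean absolute error of
the probability estimates.

The package reads the five-set benchmark layout of plain-text EEG
channel files (sets A/B = healthy, C/D = seizure-free, E = seizure; one
amplitude per line, 100 channels × 4097 samples ≈ 23.6 s per set) and
ships a synthetic generator with the same shape and class-separable
amplitude structure, so the entire pipeline is testable without any
external download.

## Worked example

```r
library(oatlmt)

cfg <- defaultRunConfig(seed = 1)   # synthetic benchmark-shaped data
cfg$evaluation$repeats <- 1         # 20 by default
res <- runPipeline(cfg)

res$sampling$A$plan
#> AllocationPlan: n = 3287 over 4 segments: 826/822/820/819

res$report
#> PerformanceReport: LMT, 10-fold CV x 1 repeat(s)
#>              sensitivity specificity precision fMeasure roc
#> healthy               99       100.0    100.00     99.5   1
#> seizure-free         100        99.5     99.01     99.5   1
#> seizure              100       100.0    100.00    100.0   1
#> accuracy 99.67%  kappa 0.995  MAE 0.0090
```

The allocation plan shows the per-segment sample sizes for set A: 3287
rows out of 4097, spread over the four 5.9-s segments according to their
variability. The report pools the out-of-fold predictions of all 300
channels (100 per class): on the default synthetic data the logistic
model tree recovers the three classes almost perfectly; one healthy
channel is misread as seizure-free.

To compare all three classifiers on the identical feature matrix and
fold plans:

```r
compareClassifiers(cfg)$ranking
```

For real data in the benchmark layout, point the configuration at a
directory with subdirectories `A`–`E` of channel files:

```r
cfg$data <- list(source = "directory", directory = "path/to/eeg")
```

A command-line front end with subcommands `synth`, `sample`, `features`,
`evaluate`, `run` and `compare` is installed under
`system.file("scripts", "oatlmt", package = "oatlmt")`.

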