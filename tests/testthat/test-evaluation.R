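test_that("stratified folds balance classes and partition the data", {
    y <- rep(classLevels(), each = 100)
    folds <- makeStratifiedFolds(y, 10, seed = 3)
    expect_length(folds, 10L)
    for (f in folds) {
        expect_length(f, 30L)
        expect_equal(as.vector(table(y[f])), rep(10L, 3))
    }
    all <- sort(unlist(folds))
    expect_identical(all, seq_along(y))  # partition, pairwise disjoint

    expect_identical(makeStratifiedFolds(y, 1)[[1]], seq_along(y))
    expect_error(makeStratifiedFolds(rep(c("a", "b"), c(3, 50)), 5),
                 "smaller than k")
    expect_identical(makeStratifiedFolds(y, 10, seed = 3), folds)
})

test_that("confusion matrices accumulate actual x predicted counts", {
    a <- c("x", "x", "y", "y", "z")
    expect_equal(diag(confusionFromPredictions(a, a)), c(x = 2, y = 2, z = 1))
    cm <- confusionFromPredictions(a, rep("x", 5))
    expect_equal(sum(cm[, "x"]), 5)
    expect_equal(sum(cm[, c("y", "z")]), 0)
    expect_equal(sum(cm), length(a))
    expect_error(confusionFromPredictions(a, c("x", "x", "y", "q", "z"),
                                          classes = c("x", "y", "z")),
                 "unknown label")
})

test_that("per-class metrics reduce one-vs-rest correctly", {
    cm <- matrix(c(8, 0, 0, 0, 5, 0, 0, 0, 7), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    for (cl in c("a", "b", "c"))
        expect_equal(as.numeric(classMetrics(cm, cl)), rep(100, 4))

    # all predicted as one class: undefined precisions reported as 0
    cm2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    cm2["a", "a"] <- 5; cm2["b", "a"] <- 5
    m <- classMetrics(cm2, "b")
    expect_equal(as.numeric(m), c(0, 100, 0, 0))
    expect_true(attr(m, "degenerate"))
})

test_that("kappa is 1 for perfect and 0 for marginal-random agreement", {
    perfect <- diag(c(10, 20, 30))
    rownames(perfect) <- colnames(perfect) <- classLevels()
    expect_equal(cohensKappa(perfect), 1)
    # independence: counts proportional to row x column marginals
    indep <- outer(c(10, 20, 30), c(30, 20, 10)) / 60
    expect_equal(cohensKappa(indep), 0)
})

test_that("MAE of a hard one-class predictor on balanced data is 4/9", {
    n <- 30
    act <- rep(c("a", "b", "c"), each = n / 3)
    proba <- matrix(0, n, 3, dimnames = list(NULL, c("a", "b", "c")))
    proba[, "a"] <- 1
    cm <- confusionFromPredictions(act, rep("a", n))
    om <- overallMetrics(cm, proba, act)
    expect_equal(om$overall[["mae"]], 4 / 9)
    expect_equal(om$overall[["accuracy"]], 100 / 3, tolerance = 1e-9)
})

test_that("metrics agree with reference implementations on fuzzed input", {
    skip_if_not_installed("caret")
    skip_if_not_installed("pROC")
    for (seed in 1:30) {
        cm <- randomConfusion(seed)
        ours <- overallMetrics(cm)$perClass
        ref <- caret::confusionMatrix(as.table(t(cm)))$byClass
        expect_equal(ours$sensitivity / 100, unname(ref[, "Sensitivity"]),
                     tolerance = 1e-9)
        expect_equal(ours$specificity / 100, unname(ref[, "Specificity"]),
                     tolerance = 1e-9)
        expect_equal(cohensKappa(cm),
                     e1071::classAgreement(cm)$kappa, tolerance = 1e-9)
    }
    set.seed(77)
    for (i in 1:20) {
        sc <- runif(50)
        lab <- runif(50) < 0.4
        if (length(unique(lab)) < 2) next
        expect_equal(oatlmt:::.rocAUC(sc, lab),
                     as.numeric(pROC::auc(lab, sc, direction = "<",
                                          levels = c(FALSE, TRUE),
                                          quiet = TRUE)),
                     tolerance = 1e-9)
    }
})

test_that("pooled accuracy equals the instance-weighted fold mean", {
    set.seed(5)
    y <- sample(classLevels(), 113, replace = TRUE)
    pred <- ifelse(runif(113) < 0.7, y,
                   sample(classLevels(), 113, replace = TRUE))
    folds <- makeStratifiedFolds(y, 4, seed = 1)
    pooled <- overallMetrics(
        confusionFromPredictions(y, pred))$overall[["accuracy"]]
    byFold <- vapply(folds, function(f) mean(y[f] == pred[f]), numeric(1))
    expect_equal(pooled / 100,
                 sum(byFold * lengths(folds)) / length(y))
})

test_that("cross-validation is perfect on separable features and deterministic", {
    fm <- smallFeatureMatrix(seed = 2, nPerClass = 30, sep = 8)
    rep1 <- crossValidate(fm, classifierSpec("MLR"), k = 5, seed = 4)
    expect_equal(overallSummary(rep1)[["accuracy"]], 100)
    expect_equal(overallSummary(rep1)[["kappa"]], 1)
    expect_lt(overallSummary(rep1)[["mae"]], 0.05)
    rep2 <- crossValidate(fm, classifierSpec("MLR"), k = 5, seed = 4)
    expect_identical(overallSummary(rep1), overallSummary(rep2))
    expect_identical(rep1@confusion, rep2@confusion)
})

test_that("label-shuffled features score at chance", {
    fm <- smallFeatureMatrix(seed = 6, nPerClass = 30, sep = 8)
    accs <- vapply(1:10, function(sd) {
        set.seed(sd)
        shuffled <- FeatureMatrix(featureValues(fm),
                                  sample(as.character(classLabels(fm))),
                                  setIds(fm))
        overallSummary(crossValidate(shuffled, classifierSpec("MLR"),
                                     k = 5, seed = sd))[["accuracy"]]
    }, numeric(1))
    expect_lt(abs(mean(accs) - 100 / 3), 5)
})

test_that("repeated experiments average their repeats", {
    fm <- smallFeatureMatrix(seed = 9, nPerClass = 20, sep = 2.5)
    single <- crossValidate(fm, classifierSpec("MLR"), k = 5,
                            seed = oatlmt:::.deriveSeed(3, "repeat", 1))
    reps1 <- repeatExperiment(fm, classifierSpec("MLR"), k = 5,
                              nRepeats = 1, baseSeed = 3)
    expect_identical(overallSummary(reps1), overallSummary(single))

    reps <- repeatExperiment(fm, classifierSpec("MLR"), k = 5,
                             nRepeats = 4, baseSeed = 3)
    acc <- reps@perRepeat$accuracy
    expect_equal(overallSummary(reps)[["accuracy"]], mean(acc))
    expect_gte(overallSummary(reps)[["accuracy"]], min(acc))
    expect_lte(overallSummary(reps)[["accuracy"]], max(acc))
    expect_equal(nrow(reps@perRepeat), 4L)
    expect_false(is.na(reps@sdOverall[["accuracy"]]))
})

test_that("averaging over more repeats stabilises the estimate", {
    fm <- smallFeatureMatrix(seed = 12, nPerClass = 20, sep = 2)
    one <- vapply(1:6, function(t)
        overallSummary(repeatExperiment(fm, classifierSpec("MLR"), k = 5,
                                        nRepeats = 1, baseSeed = 100 + t)
                       )[["accuracy"]], numeric(1))
    four <- vapply(1:6, function(t)
        overallSummary(repeatExperiment(fm, classifierSpec("MLR"), k = 5,
                                        nRepeats = 4, baseSeed = 200 + t)
                       )[["accuracy"]], numeric(1))
    expect_lt(sd(four), sd(one) + 1e-9)
})

test_that("holdout evaluation uses the requested stratified split", {
    fm <- smallFeatureMatrix(seed = 8, nPerClass = 30, sep = 8)
    rep <- holdoutEvaluate(fm, classifierSpec("MLR"),
                           trainFraction = 5 / 6, seed = 2)
    expect_equal(sum(rep@confusion), 15)  # 90 rows, 1/6 held out
    expect_equal(overallSummary(rep)[["accuracy"]], 100)
})

test_that("report export writers produce readable artifacts", {
    fm <- smallFeatureMatrix(seed = 13, nPerClass = 20, sep = 8)
    rep <- crossValidate(fm, classifierSpec("MLR"), k = 5, seed = 1)
    j <- withr::local_tempfile(fileext = ".json")
    cs <- withr::local_tempfile(fileext = ".csv")
    writeReportJSON(rep, j)
    parsed <- jsonlite::read_json(j)
    expect_equal(parsed$overall$accuracy, 100)
    writeReportCSV(rep, cs)
    df <- utils::read.csv(cs)
    expect_equal(nrow(df), 4L)  # three classes + Overall
    expect_identical(df$class[4], "Overall")
})
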