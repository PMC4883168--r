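test_that("hand-computed feature values are reproduced exactly", {
    f <- extractFeatures(c(1, 2, 2, 5))
    expect_equal(unname(f["X_Mean"]), 2.5)
    expect_equal(unname(f["X_Me"]), 2)
    expect_equal(unname(f["X_Mo"]), 2)
    expect_equal(unname(f["X_SD"]), sqrt(3))
    expect_equal(unname(f["X_Q1"]), 1.75)
    expect_equal(unname(f["X_Q3"]), 2.75)
    expect_equal(unname(f["X_IQR"]), 1)
    expect_equal(unname(f["X_beta1"]), 0.8888889, tolerance = 1e-6)
    expect_equal(unname(f["X_beta2"]), 2.1851852, tolerance = 1e-6)
    expect_equal(unname(f["X_Min"]), 1)
    expect_equal(unname(f["X_Max"]), 5)
})

test_that("constant input is flagged degenerate with zero shape statistics", {
    f <- extractFeatures(c(5, 5, 5, 5))
    expect_equal(as.numeric(f), c(5, 5, 5, 0, 5, 5, 0, 0, 0, 5, 5))
    expect_true(attr(f, "degenerate"))
})

test_that("moment statistics agree with an independent implementation", {
    for (seed in 1:20) {
        set.seed(seed)
        x <- rnorm(200, sd = runif(1, 0.5, 50))
        f <- extractFeatures(x)
        expect_equal(unname(f["X_beta1"]),
                     e1071::skewness(x, type = 1), tolerance = 1e-12)
        expect_equal(unname(f["X_beta2"]),
                     e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
        expect_equal(unname(f[c("X_Q1", "X_Q3")]),
                     unname(quantile(x, c(0.25, 0.75), type = 7)),
                     tolerance = 1e-12)
    }
})

test_that("standard normal samples have skewness 0 and kurtosis 3", {
    set.seed(99)
    x <- rnorm(1e5)
    f <- extractFeatures(x)
    expect_lt(abs(f[["X_beta1"]]), 0.1)
    expect_lt(abs(f[["X_beta2"]] - 3), 0.2)
})

test_that("features are affine-equivariant and order-invariant", {
    set.seed(42)
    for (i in 1:10) {
        x <- rnorm(60, mean = runif(1, -5, 5), sd = runif(1, 0.5, 5))
        a <- runif(1, 0.5, 3); b <- runif(1, -10, 10)
        fx <- extractFeatures(x)
        fy <- extractFeatures(a * x + b)
        shift <- c("X_Mean", "X_Me", "X_Q1", "X_Q3", "X_Min", "X_Max")
        expect_equal(unname(fy[shift]), unname(a * fx[shift] + b),
                     tolerance = 1e-10)
        expect_equal(fy[["X_SD"]], a * fx[["X_SD"]], tolerance = 1e-10)
        expect_equal(fy[["X_IQR"]], a * fx[["X_IQR"]], tolerance = 1e-10)
        expect_equal(fy[["X_beta1"]], fx[["X_beta1"]], tolerance = 1e-10)
        expect_equal(fy[["X_beta2"]], fx[["X_beta2"]], tolerance = 1e-10)
        # (the rounded-integer mode is not affine-equivariant on
        #  continuous data and is deliberately left out here)
        perm <- extractFeatures(sample(x))
        expect_equal(unname(perm), unname(fx))
    }
})

test_that("quantile sandwich holds on fuzzed inputs", {
    set.seed(7)
    for (i in 1:100) {
        x <- switch(1 + i %% 4,
                    rnorm(30), rexp(30), round(rt(30, 2)), rpois(30, 3))
        f <- extractFeatures(x)
        expect_true(f[["X_Min"]] <= f[["X_Q1"]] + 1e-12)
        expect_true(f[["X_Q1"]] <= f[["X_Me"]] + 1e-12)
        expect_true(f[["X_Me"]] <= f[["X_Q3"]] + 1e-12)
        expect_true(f[["X_Q3"]] <= f[["X_Max"]] + 1e-12)
        expect_gte(f[["X_IQR"]], 0)
        expect_gte(f[["X_SD"]], 0)
    }
})

test_that("tied rounded values take the smallest mode", {
    expect_equal(extractFeatures(c(1, 1, 3, 3))[["X_Mo"]], 1)
    expect_equal(extractFeatures(c(2.4, 1.6, 7, 8))[["X_Mo"]], 2)
})

test_that("input validation rejects short or non-finite sequences", {
    expect_error(extractFeatures(1), "at least 2")
    expect_error(extractFeatures(c(1, NA, 3)), "non-finite")
    expect_error(extractFeatures(c(1, Inf)), "non-finite")
})

test_that("per-class matrices have one row per channel", {
    rec <- tinyRecording(nT = 50, nCh = 7, setId = "E")
    fm <- featuresPerClass(rec)
    expect_equal(dim(featureValues(fm)), c(7L, 11L))
    expect_true(all(classLabels(fm) == "seizure"))
    expect_true(all(setIds(fm) == "E"))

    # duplicating channels doubles rows, values unchanged
    rec2 <- EEGRecording(cbind(signalMatrix(rec), signalMatrix(rec)),
                         setId = "E", durationSeconds = 5)
    fm2 <- featuresPerClass(rec2)
    expect_equal(nrow(featureValues(fm2)), 14L)
    expect_equal(unname(featureValues(fm2)[1:7, ]),
                 unname(featureValues(fm)))

    one <- EEGRecording(matrix(rnorm(30), 30, 1), setId = "E",
                        durationSeconds = 1)
    expect_equal(dim(featureValues(featuresPerClass(one))), c(1L, 11L))
})

test_that("assembleFullMatrix stacks classes in canonical order", {
    h <- featuresPerClass(tinyRecording(20, 3, "A", seed = 1))
    sf <- featuresPerClass(tinyRecording(20, 4, "C", seed = 2))
    sz <- featuresPerClass(tinyRecording(20, 5, "E", seed = 3))
    # deliberately shuffled input order
    fm <- assembleFullMatrix(list(sz, h, sf))
    expect_equal(nrow(featureValues(fm)), 12L)
    expect_equal(as.character(unique(classLabels(fm))), classLevels())
    expect_identical(assembleFullMatrix(list(h)), h)
    expect_equal(unname(featureValues(fm)[1:3, ]),
                 unname(featureValues(h)))
})
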