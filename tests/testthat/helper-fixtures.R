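# Programmatic fixtures shared across the test files.

# two well-separated Gaussian blobs
makeBlobs <- function(seed = 1, n = 50, sep = 4, p = 2) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n * p), n, p),
               matrix(rnorm(n * p, sep), n, p))
    colnames(X) <- sprintf("f%d", seq_len(p))
    list(X = X, y = factor(rep(c("a", "b"), each = n)))
}

# four Gaussian clusters with alternating labels (XOR layout)
makeXOR <- function(seed = 1, nPerCluster = 100, sd = 0.3) {
    set.seed(seed)
    ctr <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    X <- do.call(rbind, lapply(1:4, function(i)
        cbind(rnorm(nPerCluster, ctr[i, 1], sd),
              rnorm(nPerCluster, ctr[i, 2], sd))))
    colnames(X) <- c("x1", "x2")
    list(X = X, y = factor(rep(c("p", "p", "q", "q"),
                               each = nPerCluster)))
}

# small deterministic multichannel recording
tinyRecording <- function(nT = 40, nCh = 3, setId = "A", seed = 5) {
    set.seed(seed)
    m <- matrix(rnorm(nT * nCh, sd = 1 + seq_len(nCh)), nT, nCh)
    colnames(m) <- sprintf("c%02d", seq_len(nCh))
    EEGRecording(m, setId = setId, durationSeconds = nT / 10)
}

# well-separated 3-class feature matrix without running the EEG pipeline
smallFeatureMatrix <- function(seed = 1, nPerClass = 30, sep = 5) {
    set.seed(seed)
    centers <- rbind(rep(0, 11), rep(sep, 11), rep(2 * sep, 11))
    vals <- do.call(rbind, lapply(1:3, function(i)
        sweep(matrix(rnorm(nPerClass * 11), nPerClass, 11), 2,
              centers[i, ], "+")))
    colnames(vals) <- featureNames()
    FeatureMatrix(vals, rep(classLevels(), each = nPerClass),
                  setIds = rep(c("A", "C", "E"), each = nPerClass))
}

# benchmark-shaped dataset and its OAT feature matrix, cached per session
.benchCache <- new.env(parent = emptyenv())
benchmarkSets <- function(seed = 1) {
    key <- paste0("sets", seed)
    if (is.null(.benchCache[[key]]))
        .benchCache[[key]] <- generateBenchmarkDataset(seed = seed)
    .benchCache[[key]]
}
benchmarkFeatures <- function(seed = 1) {
    key <- paste0("fm", seed)
    if (is.null(.benchCache[[key]])) {
        sets <- benchmarkSets(seed)
        samp <- lapply(names(sets), function(sid)
            oatSampleSet(sets[[sid]], seed = seed + match(sid, LETTERS)))
        names(samp) <- names(sets)
        perClass <- lapply(
            list(combineOATSamples(list(samp$A$sample, samp$B$sample)),
                 combineOATSamples(list(samp$C$sample, samp$D$sample)),
                 samp$E$sample),
            featuresPerClass)
        .benchCache[[key]] <- list(sampling = samp,
                                   fm = assembleFullMatrix(perClass))
    }
    .benchCache[[key]]
}

# random confusion matrix over the three classes
randomConfusion <- function(seed, maxCount = 60) {
    set.seed(seed)
    m <- matrix(rpois(9, lambda = runif(1, 2, maxCount)), 3, 3,
                dimnames = list(classLevels(), classLevels()))
    # keep every actual class present
    diag(m) <- diag(m) + 1L
    m
}
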