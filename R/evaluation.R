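#' Stratified fold assignment
#'
#' Partitions instances into `k` folds preserving class proportions:
#' within each class, instances are shuffled (deterministically from
#' `seed`) and dealt round-robin, so per-class counts differ by at most
#' one across folds.
#'
#' @param labels factor (or coercible) of class labels.
#' @param k number of folds; every class must have at least `k` members.
#' @param seed integer seed.
#' @return list of `k` integer index vectors, jointly a partition of
#'   `seq_along(labels)`.
#' @export
makeStratifiedFolds <- function(labels, k, seed = 1L) {
    y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be at least 1")
    small <- table(y) < k
    if (any(small))
        stop("class(es) smaller than k = ", k, ": ",
             paste(names(table(y))[small], collapse = ", "))
    folds <- vector("list", k)
    .withSeed(seed, {
        for (cl in levels(y)) {
            idx <- sample(which(y == cl))
            f <- rep_len(seq_len(k), length(idx))
            for (i in seq_len(k))
                folds[[i]] <- c(folds[[i]], idx[f == i])
        }
    })
    lapply(folds, sort)
}

#' Confusion matrix from label vectors
#'
#' @param actual,predicted equal-length label vectors.
#' @param classes optional class universe; values outside it are an error.
#'   Defaults to the union of levels of both inputs.
#' @return integer matrix, rows = actual, columns = predicted.
#' @export
confusionFromPredictions <- function(actual, predicted, classes = NULL) {
    if (length(actual) != length(predicted))
        stop("'actual' and 'predicted' must have equal length")
    if (is.null(classes))
        classes <- union(levels(factor(actual)), levels(factor(predicted)))
    bad <- setdiff(unique(c(as.character(actual),
                            as.character(predicted))), classes)
    if (length(bad))
        stop("unknown label(s): ", paste(bad, collapse = ", "))
    a <- factor(as.character(actual), levels = classes)
    p <- factor(as.character(predicted), levels = classes)
    m <- table(actual = a, predicted = p)
    matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

## guarded ratio: 0/0 -> 0 with a flag collected by the caller
.rate <- function(num, den) if (den == 0) 0 else num / den

#' One-vs-rest metrics of one class
#'
#' Reduces the multiclass confusion matrix to the one-vs-rest table of
#' class `cls` and returns sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F-measure
#' `2*prec*sens/(prec+sens)`, all in percent. Undefined (0/0) ratios are
#' reported as 0 with a `degenerate` attribute.
#'
#' @param cm confusion matrix from [confusionFromPredictions()].
#' @param cls class name (a row/column of `cm`).
#' @return named numeric: sensitivity, specificity, precision, fMeasure.
#' @export
classMetrics <- function(cm, cls) {
    if (!cls %in% rownames(cm)) stop("unknown class: ", cls)
    tot <- sum(cm)
    tp <- cm[cls, cls]
    fn <- sum(cm[cls, ]) - tp
    fp <- sum(cm[, cls]) - tp
    tn <- tot - tp - fn - fp
    sens <- .rate(tp, tp + fn)
    spec <- .rate(tn, tn + fp)
    prec <- .rate(tp, tp + fp)
    f <- .rate(2 * prec * sens, prec + sens)
    out <- 100 * c(sensitivity = sens, specificity = spec,
                   precision = prec, fMeasure = f)
    attr(out, "degenerate") <- (tp + fn == 0) || (tn + fp == 0) ||
        (tp + fp == 0) || (prec + sens == 0)
    out
}

## one-vs-rest ROC area by midrank statistic (equals the trapezoidal area
## over all thresholds, ties handled); NA when a class is absent
.rocAUC <- function(scores, positive) {
    n1 <- sum(positive); n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa of a confusion matrix
#'
#' @param cm confusion matrix.
#' @return numeric(1) in `[-1, 1]`.
#' @export
cohensKappa <- function(cm) {
    tot <- sum(cm)
    po <- sum(diag(cm)) / tot
    pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
    if (pe == 1) return(if (po == 1) 1 else 0)
    (po - pe) / (1 - pe)
}

#' Overall metrics from pooled predictions
#'
#' Computes total accuracy (trace of the confusion matrix), Cohen's kappa,
#' the mean absolute error of the probability estimates (mean over
#' instances and classes of `|p_hat - indicator|`), per-class one-vs-rest
#' ROC areas, and class-frequency-weighted means of the per-class
#' sensitivity / specificity / precision / F-measure / ROC.
#'
#' @param cm confusion matrix (actual x predicted).
#' @param proba matrix of class probabilities, columns named by class, or
#'   NULL (then MAE and ROC are NA).
#' @param actual actual labels matching `proba` rows.
#' @return list with `perClass` (data.frame) and `overall` (named
#'   numeric: accuracy, sensitivity, specificity, precision, fMeasure,
#'   roc, kappa, mae; rates in percent).
#' @export
overallMetrics <- function(cm, proba = NULL, actual = NULL) {
    classes <- rownames(cm)
    perClass <- as.data.frame(t(vapply(classes, function(cl)
        classMetrics(cm, cl), numeric(4))))
    rocs <- rep(NA_real_, length(classes))
    mae <- NA_real_
    if (!is.null(proba)) {
        stopifnot(!is.null(actual), nrow(proba) == length(actual))
        proba <- proba[, classes, drop = FALSE]
        act <- as.character(actual)
        ind <- matrix(0, nrow(proba), ncol(proba))
        ind[cbind(seq_along(act), match(act, classes))] <- 1
        mae <- mean(abs(proba - ind))
        rocs <- vapply(seq_along(classes), function(j)
            .rocAUC(proba[, j], act == classes[j]), numeric(1))
    }
    perClass$roc <- rocs
    wts <- rowSums(cm) / sum(cm)
    wmean <- function(v) {
        ok <- !is.na(v)
        if (!any(ok)) return(NA_real_)
        sum(v[ok] * wts[ok]) / sum(wts[ok])
    }
    overall <- c(accuracy = 100 * sum(diag(cm)) / sum(cm),
                 sensitivity = wmean(perClass$sensitivity),
                 specificity = wmean(perClass$specificity),
                 precision = wmean(perClass$precision),
                 fMeasure = wmean(perClass$fMeasure),
                 roc = wmean(perClass$roc),
                 kappa = cohensKappa(cm),
                 mae = mae)
    list(perClass = perClass, overall = overall)
}

## dispatch a ClassifierSpec to its fitting function
.fitClassifier <- function(spec, x, y, seed) {
    p <- spec@params
    if (is.null(p$seed)) p$seed <- seed
    switch(spec@name,
        LMT = do.call(fitLMT, c(list(x = x, y = y), p)),
        MLR = do.call(fitRidgeMLR,
                      c(list(x = x, y = y), p[setdiff(names(p), "seed")])),
        SVM = do.call(fitSVM, c(list(x = x, y = y), p)),
        stop("unknown classifier: ", spec@name))
}

.foldHash <- function(folds) {
    v <- unlist(folds, use.names = FALSE)
    sum(as.double(v) * seq_along(v)) %% 2147483647
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Fits the model on each training fold, predicts the held-out fold, pools
#' all out-of-fold predictions and probabilities, and computes the full
#' metric suite from the pooled results (so the confusion matrix covers
#' every instance exactly once).
#'
#' @param fm a [FeatureMatrix-class].
#' @param spec a [classifierSpec()].
#' @param k number of folds (default 10).
#' @param seed integer seed governing the fold plan and any classifier
#'   randomness.
#' @return A [PerformanceReport-class].
#' @export
crossValidate <- function(fm, spec, k = 10L, seed = 1L) {
    y <- droplevels(classLabels(fm))
    X <- featureValues(fm)
    folds <- makeStratifiedFolds(y, k, seed = .deriveSeed(seed, "folds"))
    classes <- levels(y)
    proba <- matrix(NA_real_, nrow(X), length(classes),
                    dimnames = list(NULL, classes))
    predicted <- character(nrow(X))
    for (i in seq_along(folds)) {
        test <- folds[[i]]
        train <- setdiff(seq_len(nrow(X)), test)
        fit <- .fitClassifier(spec, X[train, , drop = FALSE], y[train],
                              seed = .deriveSeed(seed, "fit", i))
        P <- predictProba(fit, X[test, , drop = FALSE])
        proba[test, colnames(P)] <- P
        predicted[test] <- as.character(predict(fit, X[test, , drop = FALSE]))
    }
    proba[is.na(proba)] <- 0
    cm <- confusionFromPredictions(y, predicted, classes = classes)
    om <- overallMetrics(cm, proba, y)
    new("PerformanceReport", perClass = om$perClass,
        overall = om$overall, confusion = cm,
        perRepeat = data.frame(),
        sdOverall = setNames(rep(NA_real_, length(om$overall)),
                             names(om$overall)),
        metadata = list(classifier = spec@name, folds = length(folds),
                        repeats = 1L, seed = seed,
                        foldHash = .foldHash(folds)))
}

#' Fixed stratified holdout evaluation
#'
#' Alternative to [crossValidate()]: a single stratified train/test split
#' with `trainFraction` of each class used for training.
#'
#' @param fm a [FeatureMatrix-class].
#' @param spec a [classifierSpec()].
#' @param trainFraction fraction of each class used for training
#'   (default 250/300).
#' @param seed integer seed.
#' @return A [PerformanceReport-class].
#' @export
holdoutEvaluate <- function(fm, spec, trainFraction = 250 / 300,
                            seed = 1L) {
    stopifnot(trainFraction > 0, trainFraction < 1)
    y <- droplevels(classLabels(fm))
    X <- featureValues(fm)
    train <- .withSeed(.deriveSeed(seed, "holdout"), {
        unlist(lapply(levels(y), function(cl) {
            idx <- which(y == cl)
            sample(idx, round(trainFraction * length(idx)))
        }))
    })
    test <- setdiff(seq_len(nrow(X)), train)
    fit <- .fitClassifier(spec, X[train, , drop = FALSE], y[train],
                          seed = .deriveSeed(seed, "fit", 0L))
    P <- predictProba(fit, X[test, , drop = FALSE])
    predicted <- as.character(predict(fit, X[test, , drop = FALSE]))
    cm <- confusionFromPredictions(y[test], predicted,
                                   classes = levels(y))
    om <- overallMetrics(cm, P, y[test])
    new("PerformanceReport", perClass = om$perClass,
        overall = om$overall, confusion = cm, perRepeat = data.frame(),
        sdOverall = setNames(rep(NA_real_, length(om$overall)),
                             names(om$overall)),
        metadata = list(classifier = spec@name, folds = NA_integer_,
                        repeats = 1L, seed = seed,
                        trainFraction = trainFraction))
}

#' Repeated cross-validation
#'
#' Runs [crossValidate()] `nRepeats` times with independently derived
#' seeds and reports the arithmetic mean of every metric, keeping the
#' per-repeat overall metrics and their standard deviation.
#'
#' @param fm a [FeatureMatrix-class].
#' @param spec a [classifierSpec()].
#' @param k folds per repeat (default 10).
#' @param nRepeats number of repeats (default 20).
#' @param baseSeed integer base seed; repeat r uses a seed derived from
#'   `(baseSeed, r)`.
#' @return A [PerformanceReport-class] with averaged metrics.
#' @export
repeatExperiment <- function(fm, spec, k = 10L, nRepeats = 20L,
                             baseSeed = 1L) {
    stopifnot(nRepeats >= 1L)
    reports <- lapply(seq_len(nRepeats), function(r)
        crossValidate(fm, spec, k = k,
                      seed = .deriveSeed(baseSeed, "repeat", r)))
    if (nRepeats == 1L) return(reports[[1L]])
    perRepeat <- as.data.frame(do.call(rbind,
        lapply(reports, function(rp) rp@overall)))
    perClassMean <- Reduce(`+`, lapply(reports, function(rp)
        as.matrix(rp@perClass))) / nRepeats
    overallMean <- colMeans(perRepeat)
    new("PerformanceReport",
        perClass = as.data.frame(perClassMean),
        overall = setNames(as.numeric(overallMean), names(overallMean)),
        confusion = reports[[1L]]@confusion,
        perRepeat = perRepeat,
        sdOverall = apply(perRepeat, 2L, stats::sd),
        metadata = list(classifier = spec@name, folds = k,
                        repeats = nRepeats, baseSeed = baseSeed))
}

#' Export a performance report
#'
#' `reportAsList` flattens a [PerformanceReport-class] for serialisation;
#' `writeReportJSON` writes it as JSON; `writeReportCSV` writes the
#' per-class table (rows in canonical class order plus "Overall") as CSV
#' in the column order sensitivity, specificity, precision, F-measure,
#' ROC, total accuracy.
#'
#' @param report a [PerformanceReport-class].
#' @param path output file.
#' @return `reportAsList`: a list; the writers return `path` invisibly.
#' @export
reportAsList <- function(report) {
    list(metadata = report@metadata,
         perClass = cbind(class = rownames(report@perClass),
                          report@perClass),
         overall = as.list(report@overall),
         sdOverall = as.list(report@sdOverall),
         perRepeat = report@perRepeat,
         confusion = report@confusion)
}

#' @rdname reportAsList
#' @export
writeReportJSON <- function(report, path) {
    jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}

#' @rdname reportAsList
#' @export
writeReportCSV <- function(report, path) {
    pc <- report@perClass
    ov <- report@overall
    df <- rbind(pc[, c("sensitivity", "specificity", "precision",
                       "fMeasure", "roc")],
                Overall = ov[c("sensitivity", "specificity", "precision",
                               "fMeasure", "roc")])
    df$totalAccuracy <- c(rep(NA, nrow(pc)), ov[["accuracy"]])
    utils::write.csv(cbind(class = rownames(df), df), path,
                     row.names = FALSE)
    invisible(path)
}
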