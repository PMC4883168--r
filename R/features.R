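#' Eleven descriptive statistics of an amplitude sequence
#'
#' Computes, in column order: mean, median, mode, standard deviation
#' (divisor n - 1), first and third quartile, inter-quartile range,
#' skewness, kurtosis, minimum and maximum. Conventions (frozen, see the
#' vignette): quartiles by linear interpolation of order statistics with
#' plotting position (i - 1)/(n - 1) (the default sample-quantile type of
#' most numerical environments); the mode is the most frequent value after
#' rounding to the nearest integer, smallest value on ties; skewness
#' `m3 / m2^(3/2)` and non-excess kurtosis `m4 / m2^2` (normal -> 3) use
#' biased central moments (divisor n). A zero-variance input yields
#' skewness = kurtosis = 0 and sets the `degenerate` attribute.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param quantileType sample-quantile type passed to [stats::quantile()]
#'   (default 7, the interpolation convention above).
#' @param excessKurtosis if TRUE report kurtosis - 3 instead.
#' @return named numeric vector of length 11 (names [featureNames()]),
#'   with attribute `degenerate` (logical).
#' @examples
#' extractFeatures(c(1, 2, 2, 5))
#' @export
extractFeatures <- function(values, quantileType = 7L,
                            excessKurtosis = FALSE) {
    if (length(values) < 2L)
        stop("need at least 2 values, got ", length(values))
    if (!all(is.finite(values)))
        stop("input contains non-finite values")
    n <- length(values)
    mu <- mean(values)
    qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75),
                                 type = quantileType, names = FALSE))
    rounded <- round(values)
    tab <- table(rounded)
    modeVal <- as.numeric(names(tab)[which.max(tab)])  # smallest on ties
    m2 <- mean((values - mu)^2)
    degenerate <- m2 == 0
    if (degenerate) {
        skew <- 0; kurt <- 0
    } else {
        skew <- mean((values - mu)^3) / m2^1.5
        kurt <- mean((values - mu)^4) / m2^2
        if (excessKurtosis) kurt <- kurt - 3
    }
    out <- c(mu, qs[2L], modeVal, stats::sd(values), qs[1L], qs[3L],
             qs[3L] - qs[1L], skew, kurt, min(values), max(values))
    names(out) <- .FEATURE_NAMES
    attr(out, "degenerate") <- degenerate
    out
}

#' Per-channel features of one class sample
#'
#' Applies [extractFeatures()] to every channel of an OAT sample (or any
#' recording-shaped matrix): one row per channel, labelled with the class.
#'
#' @param sample an [OATSample-class] or [EEGRecording-class].
#' @param classLabel class for every row; defaults to the sample's label.
#' @param ... passed on to [extractFeatures()].
#' @return A [FeatureMatrix-class] with `nChannels` rows.
#' @export
featuresPerClass <- function(sample, classLabel = NULL, ...) {
    m <- signalMatrix(sample)
    if (nrow(m) < 2L) stop("sample must contain at least 2 rows")
    if (is.null(classLabel)) classLabel <- classLabel(sample)
    rows <- lapply(seq_len(ncol(m)), function(j)
        extractFeatures(m[, j], ...))
    vals <- do.call(rbind, rows)
    rownames(vals) <- colnames(m)
    FeatureMatrix(vals, classLabels = rep(classLabel, ncol(m)),
                  setIds = setId(sample),
                  degenerate = vapply(rows, attr, logical(1),
                                      "degenerate"))
}

#' Stack per-class feature matrices into the full matrix
#'
#' Row-wise concatenation in the canonical class order healthy,
#' seizure-free, seizure (inputs are reordered accordingly; within a class,
#' input order is kept).
#'
#' @param perClass list of [FeatureMatrix-class] objects with identical
#'   columns.
#' @return A [FeatureMatrix-class].
#' @export
assembleFullMatrix <- function(perClass) {
    if (!length(perClass)) stop("need at least one feature matrix")
    cols <- lapply(perClass, function(f) colnames(featureValues(f)))
    if (length(unique(cols)) > 1L)
        stop("feature matrices have mismatching columns")
    firstClass <- vapply(perClass, function(f)
        as.character(classLabels(f)[1L]), character(1))
    ord <- order(match(firstClass, .CLASS_LEVELS))
    perClass <- perClass[ord]
    FeatureMatrix(
        do.call(rbind, lapply(perClass, featureValues)),
        classLabels = unlist(lapply(perClass, function(f)
            as.character(classLabels(f)))),
        setIds = unlist(lapply(perClass, setIds)),
        degenerate = unlist(lapply(perClass, function(f) f@degenerate)))
}
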