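#' @import methods
#' @importFrom stats predict setNames
NULL

## canonical class labels, in the fixed ordering used for tie-breaks
.CLASS_LEVELS <- c("healthy", "seizure-free", "seizure")

## benchmark set -> diagnostic class
.SET_CLASS_MAP <- c(A = "healthy", B = "healthy",
                    C = "seizure-free", D = "seizure-free",
                    E = "seizure")

.FEATURE_NAMES <- c("X_Mean", "X_Me", "X_Mo", "X_SD", "X_Q1", "X_Q3",
                    "X_IQR", "X_beta1", "X_beta2", "X_Min", "X_Max")

#' Canonical class labels and feature names
#'
#' `classLevels()` returns the three diagnostic classes in their fixed order
#' (the order also used to break prediction ties); `featureNames()` returns
#' the names of the eleven per-channel statistics in column order.
#'
#' @return A character vector.
#' @examples
#' classLevels()
#' featureNames()
#' @export
classLevels <- function() .CLASS_LEVELS

#' @rdname classLevels
#' @export
featureNames <- function() .FEATURE_NAMES

#' EEGRecording: one class-set of multichannel EEG
#'
#' Stores a single benchmark set (e.g. set A) as a numeric matrix of
#' time points x channels (amplitudes in microvolts), together with the set
#' identifier, its diagnostic class and the recording duration. The sampling
#' rate is derived as `nTimepoints / durationSeconds` and is metadata only;
#' no operation in the pipeline resamples or filters.
#'
#' @slot samples numeric matrix, time points in rows, channels in columns
#'   (column names are channel identifiers).
#' @slot setId character(1), e.g. "A".."E" or a synthetic label.
#' @slot classLabel character(1), one of [classLevels()].
#' @slot durationSeconds numeric(1), recording length in seconds.
#' @export
setClass("EEGRecording",
    representation(samples = "matrix", setId = "character",
                   classLabel = "character", durationSeconds = "numeric"))

setValidity("EEGRecording", function(object) {
    msg <- character()
    if (!is.numeric(object@samples) || nrow(object@samples) < 1L ||
        ncol(object@samples) < 1L)
        msg <- c(msg, "'samples' must be a non-empty numeric matrix")
    else if (!all(is.finite(object@samples)))
        msg <- c(msg, "'samples' contains non-finite values")
    if (length(object@classLabel) != 1L ||
        !object@classLabel %in% .CLASS_LEVELS)
        msg <- c(msg, paste0("'classLabel' must be one of: ",
                             paste(.CLASS_LEVELS, collapse = ", ")))
    if (length(object@setId) != 1L || !nzchar(object@setId))
        msg <- c(msg, "'setId' must be a non-empty string")
    else if (object@setId %in% names(.SET_CLASS_MAP) &&
             length(object@classLabel) == 1L &&
             !identical(unname(.SET_CLASS_MAP[object@setId]),
                        object@classLabel))
        msg <- c(msg, sprintf("set '%s' must carry class '%s'",
                              object@setId, .SET_CLASS_MAP[object@setId]))
    if (length(object@durationSeconds) != 1L ||
        !is.finite(object@durationSeconds) || object@durationSeconds <= 0)
        msg <- c(msg, "'durationSeconds' must be a positive number")
    if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples numeric matrix (time points x channels) or a list of
#'   equal-length numeric vectors, one per channel.
#' @param setId set identifier; for "A".."E" the class label is implied.
#' @param classLabel diagnostic class; defaults to the label implied by
#'   `setId` when that is one of "A".."E".
#' @param durationSeconds recording duration (default 23.6 s, the benchmark
#'   convention for 4097-sample channels).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 100, 2), setId = "A")
#' samplingRate(rec)
#' @export
EEGRecording <- function(samples, setId, classLabel = NULL,
                         durationSeconds = 23.6) {
    if (is.list(samples)) {
        len <- lengths(samples)
        if (length(unique(len)) > 1L)
            stop("all channels must have the same length; got lengths ",
                 paste(unique(len), collapse = ", "))
        samples <- do.call(cbind, samples)
    }
    samples <- as.matrix(samples)
    storage.mode(samples) <- "double"
    if (is.null(colnames(samples)))
        colnames(samples) <- sprintf("ch%03d", seq_len(ncol(samples)))
    if (is.null(classLabel)) {
        if (!setId %in% names(.SET_CLASS_MAP))
            stop("'classLabel' must be given when setId is not one of A-E")
        classLabel <- unname(.SET_CLASS_MAP[setId])
    }
    new("EEGRecording", samples = samples, setId = setId,
        classLabel = classLabel, durationSeconds = durationSeconds)
}

#' SegmentStats: per-segment, per-channel variability
#'
#' Result of segmenting a recording: the segment boundaries, the number of
#' time points per segment and the sample variance (divisor n-1) of every
#' channel within every segment. These are the ingredients of the
#' optimum-allocation rule, whose weight for segment i is
#' `N_i * sqrt(sum_j S_ij^2)`.
#'
#' @slot bounds integer matrix (k x 2), 1-based inclusive start/end rows.
#' @slot variances numeric matrix (k x channels) of within-segment sample
#'   variances, in microvolts squared.
#' @export
setClass("SegmentStats",
    representation(bounds = "matrix", variances = "matrix"))

setValidity("SegmentStats", function(object) {
    b <- object@bounds
    msg <- character()
    if (ncol(b) != 2L || nrow(b) < 1L)
        msg <- c(msg, "'bounds' must be a k x 2 matrix")
    else {
        if (any(b[, 2L] < b[, 1L]))
            msg <- c(msg, "segment ends must not precede starts")
        if (nrow(b) > 1L && any(b[-1L, 1L] != b[-nrow(b), 2L] + 1L))
            msg <- c(msg, "segments must be contiguous and non-overlapping")
    }
    if (nrow(object@variances) != nrow(b))
        msg <- c(msg, "'variances' must have one row per segment")
    if (any(object@variances < 0))
        msg <- c(msg, "variances must be non-negative")
    if (length(msg)) msg else TRUE
})

#' AllocationPlan: integer sample allocation across segments
#'
#' @slot allocations integer vector, sample size per segment; sums to `n`.
#' @slot n integer(1), total sample size for the recording.
#' @slot weights numeric vector, the real-valued allocation weights
#'   `N_i * sqrt(sum_j S_ij^2)` before rounding.
#' @slot fallback logical(1), TRUE when all weights were zero and the plan
#'   fell back to allocation proportional to segment length.
#' @export
setClass("AllocationPlan",
    representation(allocations = "integer", n = "integer",
                   weights = "numeric", fallback = "logical"))

setValidity("AllocationPlan", function(object) {
    msg <- character()
    if (sum(object@allocations) != object@n)
        msg <- c(msg, "allocations must sum to n")
    if (any(object@allocations < 0L))
        msg <- c(msg, "allocations must be non-negative")
    if (length(object@weights) != length(object@allocations))
        msg <- c(msg, "one weight per segment required")
    if (length(msg)) msg else TRUE
})

#' OATSample: the selected time points of a recording
#'
#' Rows drawn by simple random sampling without replacement within each
#' segment, in ascending time order, across all channels. Combined samples
#' (several sets of the same class) concatenate rows channel-wise.
#'
#' @slot setId character(1); combined samples join ids with "+".
#' @slot classLabel character(1).
#' @slot rows list of integer vectors, the selected 1-based row indices per
#'   segment (per source segment after combination), each sorted, no
#'   duplicates.
#' @slot data numeric matrix, selected time points x channels.
#' @export
setClass("OATSample",
    representation(setId = "character", classLabel = "character",
                   rows = "list", data = "matrix"))

setValidity("OATSample", function(object) {
    msg <- character()
    if (sum(lengths(object@rows)) != nrow(object@data))
        msg <- c(msg, "row count of 'data' must equal total selected rows")
    bad <- vapply(object@rows, function(r)
        is.unsorted(r, strictly = TRUE), logical(1))
    if (any(bad))
        msg <- c(msg, "selected rows must be sorted and duplicate-free")
    if (length(msg)) msg else TRUE
})

#' FeatureMatrix: channels x 11 statistics with class labels
#'
#' One row per channel; the eleven columns are the per-channel statistics
#' named by [featureNames()]. Rows carry the diagnostic class and the set
#' they came from. `degenerate` flags rows whose input had zero variance
#' (skewness/kurtosis reported as 0 by convention).
#'
#' @slot values numeric matrix (n x 11), columns named as [featureNames()].
#' @slot classLabels factor with levels [classLevels()].
#' @slot setIds character vector, provenance per row.
#' @slot degenerate logical vector, zero-variance flag per row.
#' @export
setClass("FeatureMatrix",
    representation(values = "matrix", classLabels = "factor",
                   setIds = "character", degenerate = "logical"))

setValidity("FeatureMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (ncol(v) != length(.FEATURE_NAMES) ||
        !identical(colnames(v), .FEATURE_NAMES))
        msg <- c(msg, sprintf("'values' must have the %d named feature columns",
                              length(.FEATURE_NAMES)))
    if (anyNA(v) || !all(is.finite(v)))
        msg <- c(msg, "'values' must be finite with no missing entries")
    if (length(object@classLabels) != nrow(v) ||
        !identical(levels(object@classLabels), .CLASS_LEVELS))
        msg <- c(msg, "'classLabels' must be one factor value per row with the canonical levels")
    if (length(object@setIds) != nrow(v))
        msg <- c(msg, "'setIds' must have one entry per row")
    if (length(object@degenerate) != nrow(v))
        msg <- c(msg, "'degenerate' must have one flag per row")
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix with the eleven feature columns.
#' @param classLabels character or factor of diagnostic classes, one per row.
#' @param setIds character vector of set identifiers, one per row (recycled
#'   from length 1).
#' @param degenerate logical vector of zero-variance flags (default all
#'   FALSE).
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, classLabels, setIds,
                          degenerate = rep(FALSE, nrow(values))) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (length(setIds) == 1L) setIds <- rep(setIds, nrow(values))
    new("FeatureMatrix", values = values,
        classLabels = factor(as.character(classLabels),
                             levels = .CLASS_LEVELS),
        setIds = as.character(setIds), degenerate = degenerate)
}

#' ClassifierSpec: which model to fit and with what hyperparameters
#'
#' @slot name character(1), one of "LMT", "MLR", "SVM".
#' @slot params named list of hyperparameters merged over the model's
#'   defaults (see [fitLMT()], [fitRidgeMLR()], [fitSVM()]).
#' @export
setClass("ClassifierSpec",
    representation(name = "character", params = "list"))

setValidity("ClassifierSpec", function(object) {
    if (!object@name %in% c("LMT", "MLR", "SVM"))
        "name must be one of LMT, MLR, SVM" else TRUE
})

#' @param name classifier name, one of "LMT", "MLR", "SVM".
#' @param ... hyperparameters overriding the model defaults.
#' @rdname ClassifierSpec-class
#' @examples
#' classifierSpec("LMT")
#' classifierSpec("MLR", lambda = 1e-4)
#' @export
classifierSpec <- function(name, ...) {
    new("ClassifierSpec", name = toupper(name), params = list(...))
}

#' LMTModel: a fitted logistic model tree
#'
#' A decision tree whose every node carries an additive logistic model: a
#' committee of simple one-feature linear functions accumulated by
#' LogitBoost, warm-started at each child from its parent's committee.
#'
#' @slot root list, the recursive node structure.
#' @slot classes character vector of class labels in model order.
#' @slot features character vector of training feature names.
#' @slot iterations integer(1), LogitBoost iterations used per node.
#' @slot spec list of resolved hyperparameters.
#' @export
setClass("LMTModel",
    representation(root = "list", classes = "character",
                   features = "character", iterations = "integer",
                   spec = "list"))

#' RidgeMLRModel: ridge-penalised multinomial logistic regression
#'
#' Reference-class (last class) parameterisation; intercepts unpenalised;
#' features standardised internally with training-set mean/sd.
#'
#' @slot coefficients numeric matrix ((features+1) x (classes-1)).
#' @slot lambda numeric(1), ridge penalty.
#' @slot center,scale numeric vectors, the standardisation parameters.
#' @slot classes character vector of class labels in model order.
#' @slot features character vector of training feature names.
#' @slot converged logical(1).
#' @slot iterations integer(1), Newton iterations used.
#' @export
setClass("RidgeMLRModel",
    representation(coefficients = "matrix", lambda = "numeric",
                   center = "numeric", scale = "numeric",
                   classes = "character", features = "character",
                   converged = "logical", iterations = "integer"))

#' SVMModel: adapter around a libsvm fit
#'
#' Thin wrapper around [e1071::svm()] (libsvm) exposing the same
#' predict / predictProba contract as the native models.
#'
#' @slot fit the underlying e1071 model object.
#' @slot classes character vector of class labels in model order.
#' @slot features character vector of training feature names.
#' @slot spec list of resolved hyperparameters.
#' @export
setClass("SVMModel",
    representation(fit = "ANY", classes = "character",
                   features = "character", spec = "list"))

#' PerformanceReport: evaluation results
#'
#' Metrics computed from the pooled out-of-fold confusion matrix and
#' probability estimates of a (possibly repeated) stratified
#' cross-validation. Rates are stored as percentages; ROC areas, kappa and
#' MAE on their natural scales.
#'
#' @slot perClass data.frame with one row per class: sensitivity,
#'   specificity, precision, F-measure (percent) and ROC area.
#' @slot overall named numeric: accuracy, weighted sensitivity/specificity/
#'   precision/F (percent), weighted ROC, kappa, MAE.
#' @slot confusion integer matrix (actual x predicted), pooled; for repeated
#'   runs the first repeat's matrix.
#' @slot perRepeat data.frame of per-repeat overall metrics (one row per
#'   repeat).
#' @slot sdOverall named numeric, standard deviation of each overall metric
#'   across repeats (NA when a single repeat).
#' @slot metadata list: classifier name, folds, repeats, seeds.
#' @export
setClass("PerformanceReport",
    representation(perClass = "data.frame", overall = "numeric",
                   confusion = "matrix", perRepeat = "data.frame",
                   sdOverall = "numeric", metadata = "list"))
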