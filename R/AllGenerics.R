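#' Accessors for oatlmt objects
#'
#' @param x an oatlmt object.
#' @name accessors
NULL

#' @describeIn accessors time points x channels amplitude matrix of an
#'   [EEGRecording-class] or the selected rows of an [OATSample-class].
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @describeIn accessors set identifier.
#' @export
setGeneric("setId", function(x) standardGeneric("setId"))

#' @describeIn accessors diagnostic class label(s).
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @describeIn accessors recording duration in seconds.
#' @export
setGeneric("durationSeconds", function(x) standardGeneric("durationSeconds"))

#' @describeIn accessors derived sampling rate in Hz
#'   (time points / duration).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @describeIn accessors number of channels.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @describeIn accessors number of time points.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @describeIn accessors numeric matrix of feature values.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn accessors factor of per-row diagnostic classes.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @describeIn accessors per-row set provenance.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @describeIn accessors integer per-segment allocations of an
#'   [AllocationPlan-class].
#' @export
setGeneric("allocations", function(x) standardGeneric("allocations"))

#' @describeIn accessors selected row indices (list per segment) of an
#'   [OATSample-class].
#' @export
setGeneric("selectedRows", function(x) standardGeneric("selectedRows"))

#' @describeIn accessors per-class metric table of a
#'   [PerformanceReport-class].
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @describeIn accessors named overall metric vector of a
#'   [PerformanceReport-class].
#' @export
setGeneric("overallSummary", function(x) standardGeneric("overallSummary"))

#' Class-probability predictions
#'
#' Returns an n x J matrix of predicted class probabilities (columns in
#' model class order; rows sum to 1). `predict` returns the argmax label,
#' ties broken towards the earlier class in [classLevels()] order.
#'
#' @param object a fitted model ([LMTModel-class], [RidgeMLRModel-class] or
#'   [SVMModel-class]).
#' @param newdata a [FeatureMatrix-class], numeric matrix or data.frame with
#'   the training feature columns.
#' @return numeric matrix of probabilities.
#' @export
setGeneric("predictProba",
           function(object, newdata) standardGeneric("predictProba"))
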