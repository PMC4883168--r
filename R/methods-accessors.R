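#' @rdname accessors
setMethod("signalMatrix", "EEGRecording", function(x) x@samples)
#' @rdname accessors
setMethod("signalMatrix", "OATSample", function(x) x@data)

#' @rdname accessors
setMethod("setId", "EEGRecording", function(x) x@setId)
#' @rdname accessors
setMethod("setId", "OATSample", function(x) x@setId)

#' @rdname accessors
setMethod("classLabel", "EEGRecording", function(x) x@classLabel)
#' @rdname accessors
setMethod("classLabel", "OATSample", function(x) x@classLabel)

#' @rdname accessors
setMethod("durationSeconds", "EEGRecording", function(x) x@durationSeconds)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording",
          function(x) nrow(x@samples) / x@durationSeconds)

#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) ncol(x@samples))
#' @rdname accessors
setMethod("nChannels", "OATSample", function(x) ncol(x@data))

#' @rdname accessors
setMethod("nTimepoints", "EEGRecording", function(x) nrow(x@samples))

#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("classLabels", "FeatureMatrix", function(x) x@classLabels)
#' @rdname accessors
setMethod("setIds", "FeatureMatrix", function(x) x@setIds)

#' @rdname accessors
setMethod("allocations", "AllocationPlan", function(x) x@allocations)

#' @rdname accessors
setMethod("selectedRows", "OATSample", function(x) x@rows)

#' @rdname accessors
setMethod("perClassMetrics", "PerformanceReport", function(x) x@perClass)
#' @rdname accessors
setMethod("overallSummary", "PerformanceReport", function(x) x@overall)

setMethod("show", "EEGRecording", function(object) {
    cat(sprintf("EEGRecording set '%s' (%s): %d time points x %d channels, %.1f s (%.1f Hz)\n",
                object@setId, object@classLabel, nrow(object@samples),
                ncol(object@samples), object@durationSeconds,
                nrow(object@samples) / object@durationSeconds))
})

setMethod("show", "SegmentStats", function(object) {
    n <- object@bounds[, 2L] - object@bounds[, 1L] + 1L
    cat(sprintf("SegmentStats: %d segments (lengths %s), %d channels\n",
                nrow(object@bounds), paste(n, collapse = "/"),
                ncol(object@variances)))
})

setMethod("show", "AllocationPlan", function(object) {
    cat(sprintf("AllocationPlan: n = %d over %d segments: %s%s\n",
                object@n, length(object@allocations),
                paste(object@allocations, collapse = "/"),
                if (object@fallback) " [fallback: proportional]" else ""))
})

setMethod("show", "OATSample", function(object) {
    cat(sprintf("OATSample set '%s' (%s): %d selected rows x %d channels in %d segments\n",
                object@setId, object@classLabel, nrow(object@data),
                ncol(object@data), length(object@rows)))
})

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix: %d channels x %d features\n",
                nrow(object@values), ncol(object@values)))
    print(table(object@classLabels))
})

setMethod("show", "ClassifierSpec", function(object) {
    cat(sprintf("ClassifierSpec: %s", object@name))
    if (length(object@params))
        cat(" (", paste(names(object@params), unlist(object@params),
                        sep = "=", collapse = ", "), ")", sep = "")
    cat("\n")
})

setMethod("show", "LMTModel", function(object) {
    cat(sprintf("LMTModel: %d leaves, %d LogitBoost iterations/node, classes: %s\n",
                .lmtCountLeaves(object@root), object@iterations,
                paste(object@classes, collapse = ", ")))
})

setMethod("show", "RidgeMLRModel", function(object) {
    cat(sprintf("RidgeMLRModel: %d classes, %d features, lambda = %g, %s in %d iterations\n",
                length(object@classes), length(object@features),
                object@lambda,
                if (object@converged) "converged" else "NOT converged",
                object@iterations))
})

setMethod("show", "SVMModel", function(object) {
    cat(sprintf("SVMModel (libsvm adapter): %d classes, kernel=%s, cost=%g\n",
                length(object@classes), object@spec$kernel,
                object@spec$cost))
})

setMethod("show", "PerformanceReport", function(object) {
    md <- object@metadata
    cat(sprintf("PerformanceReport: %s, %d-fold CV x %d repeat(s)\n",
                if (is.null(md$classifier)) "?" else md$classifier,
                if (is.null(md$folds)) NA_integer_ else md$folds,
                if (is.null(md$repeats)) 1L else md$repeats))
    print(round(object@perClass, 2))
    ov <- object@overall
    cat(sprintf("accuracy %.2f%%  kappa %.3f  MAE %.4f\n",
                ov[["accuracy"]], ov[["kappa"]], ov[["mae"]]))
})
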