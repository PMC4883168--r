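#' Fit a support vector machine (libsvm adapter)
#'
#' Thin wrapper around [e1071::svm()] — the libsvm implementation — with
#' one-vs-one multiclass decomposition and probability outputs, exposing
#' the same predict / [predictProba()] contract as the native models.
#' Defaults: RBF kernel, `cost = 1`, `gamma = 1 / nFeatures`, features
#' scaled to training mean 0 / sd 1 inside the backend.
#'
#' @param x a [FeatureMatrix-class], numeric matrix or data.frame.
#' @param y class labels (taken from `x` when it is a FeatureMatrix).
#' @param kernel kernel name passed to the backend (default "radial").
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF kernel width (default `1 / ncol(x)`).
#' @param seed integer seed for the backend's internal probability
#'   cross-validation.
#' @return An [SVMModel-class].
#' @export
fitSVM <- function(x, y = NULL, kernel = "radial", cost = 1,
                   gamma = NULL, seed = 1L) {
    if (!requireNamespace("e1071", quietly = TRUE))
        stop("the SVM backend requires the 'e1071' package")
    xy <- .resolveXY(x, y)
    X <- xy$X; yf <- xy$y
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    fit <- .withSeed(seed,
        e1071::svm(X, yf, kernel = kernel, cost = cost, gamma = gamma,
                   probability = TRUE, scale = TRUE))
    new("SVMModel", fit = fit, classes = levels(yf),
        features = colnames(X) %||% sprintf("V%d", seq_len(ncol(X))),
        spec = list(kernel = kernel, cost = cost, gamma = gamma,
                    seed = seed))
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "SVMModel", function(object, newdata) {
    X <- .resolveNewdata(object, newdata)
    pr <- predict(object@fit, X, probability = TRUE)
    P <- attr(pr, "probabilities")
    P <- P[, object@classes, drop = FALSE]  # backend orders by fit
    P / rowSums(P)
})

#' @param object a fitted model.
#' @param newdata feature data with the training columns.
#' @describeIn fitSVM predicted class labels (argmax of the class
#'   probabilities).
#' @export
setMethod("predict", "SVMModel", function(object, newdata) {
    P <- predictProba(object, newdata)
    factor(object@classes[max.col(P, ties.method = "first")],
           levels = object@classes)
})
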