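## Versioned JSON persistence for the native models. The SVM adapter is a
## wrapper around an external backend and is not serialised here.

.nodeToList <- function(node) {
    out <- list(counts = node$counts, n = node$n, err = node$err,
                leaf = node$leaf,
                feat = apply(node$comm$feat, 1L, as.integer,
                             simplify = FALSE),
                a = apply(node$comm$a, 1L, as.numeric, simplify = FALSE),
                b = apply(node$comm$b, 1L, as.numeric, simplify = FALSE))
    if (!node$leaf) {
        out$feature <- node$feature
        out$value <- node$value
        out$left <- .nodeToList(node$left)
        out$right <- .nodeToList(node$right)
    }
    out
}

.nodeFromList <- function(l, J) {
    asMat <- function(rows, mode) {
        if (!length(rows)) return(matrix(vector(mode, 0), 0L, J))
        m <- do.call(rbind, lapply(rows, unlist))
        storage.mode(m) <- mode
        m
    }
    node <- list(counts = unlist(l$counts), n = l$n, err = l$err,
                 leaf = l$leaf,
                 comm = list(feat = asMat(l$feat, "integer"),
                             a = asMat(l$a, "double"),
                             b = asMat(l$b, "double")))
    if (!l$leaf) {
        node$feature <- l$feature
        node$value <- l$value
        node$left <- .nodeFromList(l$left, J)
        node$right <- .nodeFromList(l$right, J)
    }
    node
}

#' Save / load a fitted model as versioned JSON
#'
#' Supports [LMTModel-class] (tree structure and node committees) and
#' [RidgeMLRModel-class] (coefficients and standardisation parameters).
#' The SVM adapter delegates to an external backend and is not
#' serialisable this way.
#'
#' @param model a fitted model.
#' @param path JSON file.
#' @return `writeModelJSON` returns `path` invisibly; `readModelJSON`
#'   returns the reconstructed model.
#' @export
writeModelJSON <- function(model, path) {
    obj <- if (is(model, "LMTModel")) {
        list(type = "LMTModel", version = 1L, classes = model@classes,
             features = model@features, iterations = model@iterations,
             spec = model@spec, root = .nodeToList(model@root))
    } else if (is(model, "RidgeMLRModel")) {
        list(type = "RidgeMLRModel", version = 1L,
             classes = model@classes, features = model@features,
             lambda = model@lambda, center = model@center,
             scale = model@scale, converged = model@converged,
             iterations = model@iterations,
             coefficients = apply(model@coefficients, 1L, as.numeric,
                                  simplify = FALSE))
    } else stop("cannot serialise models of class ", class(model))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    classes <- unlist(obj$classes)
    features <- unlist(obj$features)
    if (identical(obj$type, "LMTModel")) {
        new("LMTModel", root = .nodeFromList(obj$root, length(classes)),
            classes = classes, features = features,
            iterations = as.integer(obj$iterations),
            spec = lapply(obj$spec, function(v)
                if (is.list(v)) unlist(v) else v))
    } else if (identical(obj$type, "RidgeMLRModel")) {
        K <- length(classes) - 1L
        coef <- do.call(rbind, lapply(obj$coefficients, unlist))
        dimnames(coef) <- list(c("(Intercept)", features),
                               classes[seq_len(K)])
        new("RidgeMLRModel", coefficients = coef,
            lambda = obj$lambda, center = unlist(obj$center),
            scale = unlist(obj$scale), classes = classes,
            features = features, converged = obj$converged,
            iterations = as.integer(obj$iterations))
    } else stop("unknown model type in ", path)
}
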