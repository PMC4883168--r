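## Logistic model tree: a decision tree whose nodes carry additive logistic
## models fitted by multiclass LogitBoost with simple (single-feature)
## weighted-least-squares base learners. Child nodes warm-start from the
## parent's committee; the boosting iteration count is chosen once by
## internal cross-validation at the root; the grown tree is pruned by CART
## cost-complexity pruning with internal cross-validation.

.Z_MAX <- 3  # working-response cap of the LogitBoost recursion

.softmax <- function(F) {
    E <- exp(F - apply(F, 1L, max))
    E / rowSums(E)
}

## one LogitBoost iteration's base learners: for each class the best
## single-feature WLS fit to the working response; returns J rows (feat,a,b)
.boostStep <- function(X, Xsq, y01, P) {
    J <- ncol(y01)
    feat <- integer(J); aa <- numeric(J); bb <- numeric(J)
    fstar <- matrix(0, nrow(X), J)
    for (j in seq_len(J)) {
        p <- P[, j]
        w <- pmax(p * (1 - p), 1e-12)
        z <- (y01[, j] - p) / w
        z[z > .Z_MAX] <- .Z_MAX
        z[z < -.Z_MAX] <- -.Z_MAX
        sw <- sum(w)
        swx <- crossprod(X, w)[, 1L]
        swx2 <- crossprod(Xsq, w)[, 1L]
        wz <- w * z
        swz <- sum(wz)
        swxz <- crossprod(X, wz)[, 1L]
        denom <- swx2 - swx^2 / sw
        b <- ifelse(denom > 1e-10 * pmax(swx2, 1),
                    (swxz - swx * swz / sw) / denom, 0)
        a <- (swz - b * swx) / sw
        sse <- sum(wz * z) - 2 * (a * swz + b * swxz) +
            a^2 * sw + 2 * a * b * swx + b^2 * swx2
        f <- which.min(sse)
        feat[j] <- f; aa[j] <- a[f]; bb[j] <- b[f]
        fstar[, j] <- aa[j] + bb[j] * X[, f]
    }
    list(feat = feat, a = aa, b = bb, fstar = fstar)
}

## apply one stored iteration to a score matrix
.applyStep <- function(F, X, feat, a, b) {
    J <- ncol(F)
    fstar <- X[, feat, drop = FALSE] *
        matrix(b, nrow(X), J, byrow = TRUE) +
        matrix(a, nrow(X), J, byrow = TRUE)
    F + (J - 1) / J * (fstar - rowMeans(fstar))
}

## run nIter LogitBoost iterations from scores F; optionally track the
## misclassification count on a validation set after every iteration,
## stopping early when the best count has not improved for `patience`
## iterations (remaining entries padded with the last value)
.logitboostRun <- function(X, y01, F, nIter, Xval = NULL, yvalInt = NULL,
                           patience = Inf) {
    n <- nrow(X); J <- ncol(y01)
    Xsq <- X * X
    feat <- matrix(0L, nIter, J); A <- matrix(0, nIter, J)
    B <- matrix(0, nIter, J)
    track <- !is.null(Xval)
    errs <- if (track) numeric(nIter) else NULL
    if (track) Fval <- matrix(0, nrow(Xval), J)
    best <- Inf; bestIt <- 0L; used <- nIter
    for (it in seq_len(nIter)) {
        st <- .boostStep(X, Xsq, y01, .softmax(F))
        feat[it, ] <- st$feat; A[it, ] <- st$a; B[it, ] <- st$b
        F <- F + (J - 1) / J * (st$fstar - rowMeans(st$fstar))
        if (track) {
            Fval <- .applyStep(Fval, Xval, st$feat, st$a, st$b)
            errs[it] <- sum(max.col(Fval, ties.method = "first") != yvalInt)
            if (errs[it] < best) { best <- errs[it]; bestIt <- it }
            if (it - bestIt >= patience) {
                if (it < nIter) errs[(it + 1L):nIter] <- errs[it]
                used <- it
                break
            }
        }
    }
    if (used < nIter) {
        feat <- feat[seq_len(used), , drop = FALSE]
        A <- A[seq_len(used), , drop = FALSE]
        B <- B[seq_len(used), , drop = FALSE]
    }
    list(feat = feat, a = A, b = B, F = F, errs = errs)
}

## evaluate a node committee on X, starting from scores F
.applyCommittee <- function(comm, X, F) {
    for (it in seq_len(nrow(comm$feat)))
        F <- .applyStep(F, X, comm$feat[it, ], comm$a[it, ], comm$b[it, ])
    F
}

## choose the LogitBoost iteration count by stratified cross-validation at
## the root (smallest count reaching the minimum pooled validation error)
.cvBoostIterations <- function(X, y01, yInt, maxIter, cvFolds, patience,
                               seed) {
    n <- nrow(X)
    cvFolds <- min(cvFolds, min(tabulate(yInt)))
    if (cvFolds < 2L) return(min(maxIter, 10L))
    folds <- .withSeed(seed, {
        idx <- unlist(lapply(seq_len(ncol(y01)), function(j) {
            cls <- which(yInt == j)
            sample(cls)
        }))
        split(idx, rep_len(seq_len(cvFolds), length(idx)))
    })
    total <- numeric(maxIter)
    for (f in folds) {
        tr <- setdiff(seq_len(n), f)
        r <- .logitboostRun(X[tr, , drop = FALSE],
                            y01[tr, , drop = FALSE],
                            matrix(0, length(tr), ncol(y01)), maxIter,
                            Xval = X[f, , drop = FALSE], yvalInt = yInt[f],
                            patience = patience)
        total <- total + r$errs
    }
    which.min(total)  # earliest minimum
}

## binary entropy split search; returns NULL when no split improves
.bestSplit <- function(X, yInt, J, minLeaf = 2L) {
    n <- length(yInt)
    cnt <- tabulate(yInt, J)
    ent <- function(M, tot) {
        P <- M / tot
        P[P <= 0] <- 1
        -rowSums(P * log2(P))
    }
    H0 <- ent(matrix(cnt, 1L), n)
    best <- NULL; bestGain <- 1e-9
    Y <- matrix(0, n, J); Y[cbind(seq_len(n), yInt)] <- 1
    for (f in seq_len(ncol(X))) {
        ord <- order(X[, f], method = "radix")
        xs <- X[ord, f]
        cum <- apply(Y[ord, , drop = FALSE], 2L, cumsum)
        if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
        i <- seq_len(n - 1L)
        ok <- i >= minLeaf & (n - i) >= minLeaf & xs[i] < xs[i + 1L]
        if (!any(ok)) next
        i <- i[ok]
        L <- cum[i, , drop = FALSE]
        R <- matrix(cnt, length(i), J, byrow = TRUE) - L
        gain <- H0 - (i / n * ent(L, i) + (n - i) / n * ent(R, n - i))
        gi <- which.max(gain)
        if (gain[gi] > bestGain) {
            bestGain <- gain[gi]
            best <- list(feature = f,
                         value = (xs[i[gi]] + xs[i[gi] + 1L]) / 2,
                         gain = gain[gi])
        }
    }
    best
}

## recursive node construction; F holds the accumulated parent scores of
## the instances reaching this node
.growLMTNode <- function(X, y01, yInt, F, iters, minSplit, maxDepth,
                         depth) {
    n <- nrow(X); J <- ncol(y01)
    r <- .logitboostRun(X, y01, F, iters)
    pred <- max.col(r$F, ties.method = "first")
    node <- list(counts = tabulate(yInt, J), n = n,
                 comm = list(feat = r$feat, a = r$a, b = r$b),
                 err = sum(pred != yInt), leaf = TRUE)
    if (n < minSplit || depth >= maxDepth || length(unique(yInt)) < 2L)
        return(node)
    sp <- .bestSplit(X, yInt, J)
    if (is.null(sp)) return(node)
    left <- X[, sp$feature] <= sp$value
    node$leaf <- FALSE
    node$feature <- sp$feature
    node$value <- sp$value
    node$left <- .growLMTNode(X[left, , drop = FALSE],
                              y01[left, , drop = FALSE], yInt[left],
                              r$F[left, , drop = FALSE], iters, minSplit,
                              maxDepth, depth + 1L)
    node$right <- .growLMTNode(X[!left, , drop = FALSE],
                               y01[!left, , drop = FALSE], yInt[!left],
                               r$F[!left, , drop = FALSE], iters, minSplit,
                               maxDepth, depth + 1L)
    node
}

.lmtCountLeaves <- function(node) {
    if (isTRUE(node$leaf) || is.null(node$leaf)) return(1L)
    .lmtCountLeaves(node$left) + .lmtCountLeaves(node$right)
}

## training misclassifications of the subtree's leaves
.subtreeErr <- function(node) {
    if (node$leaf) return(node$err)
    .subtreeErr(node$left) + .subtreeErr(node$right)
}

## increasing sequence of critical cost-complexity alphas of a tree
.alphaSequence <- function(node, nTotal) {
    alphas <- numeric(0)
    tree <- node
    g <- function(nd) {  # min weakest-link value in subtree
        if (nd$leaf) return(Inf)
        own <- (nd$err - .subtreeErr(nd)) /
            (nTotal * (.lmtCountLeaves(nd) - 1L))
        min(own, g(nd$left), g(nd$right))
    }
    collapse <- function(nd, alpha) {  # prune all nodes with g <= alpha
        if (nd$leaf) return(nd)
        nd$left <- collapse(nd$left, alpha)
        nd$right <- collapse(nd$right, alpha)
        gg <- (nd$err - .subtreeErr(nd)) /
            (nTotal * (.lmtCountLeaves(nd) - 1L))
        if (gg <= alpha) {
            nd$leaf <- TRUE
            nd$left <- NULL; nd$right <- NULL
            nd$feature <- NULL; nd$value <- NULL
        }
        nd
    }
    while (!tree$leaf) {
        a <- g(tree)
        alphas <- c(alphas, a)
        tree <- collapse(tree, a)
    }
    list(alphas = alphas, collapse = collapse)
}

## scores of instances routed through a (sub)tree
.lmtScores <- function(node, X, F) {
    F <- .applyCommittee(node$comm, X, F)
    if (node$leaf || nrow(X) == 0L) return(F)
    left <- X[, node$feature] <= node$value
    if (any(left))
        F[left, ] <- .lmtScores(node$left, X[left, , drop = FALSE],
                                F[left, , drop = FALSE])
    if (any(!left))
        F[!left, ] <- .lmtScores(node$right, X[!left, , drop = FALSE],
                                 F[!left, , drop = FALSE])
    F
}

## resolve (x, y) into a numeric matrix and a factor
.resolveXY <- function(x, y = NULL) {
    if (is(x, "FeatureMatrix")) {
        X <- featureValues(x)
        if (is.null(y)) y <- classLabels(x)
    } else {
        X <- as.matrix(x)
        storage.mode(X) <- "double"
    }
    if (is.null(y)) stop("labels 'y' are required")
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    if (length(y) != nrow(X))
        stop("length of 'y' must match the number of rows")
    list(X = X, y = y)
}

## resolve newdata against a model's training feature names
.resolveNewdata <- function(object, newdata) {
    X <- if (is(newdata, "FeatureMatrix")) featureValues(newdata)
         else as.matrix(newdata)
    storage.mode(X) <- "double"
    feats <- object@features
    if (!is.null(colnames(X))) {
        miss <- setdiff(feats, colnames(X))
        if (length(miss))
            stop("newdata is missing training column(s): ",
                 paste(miss, collapse = ", "))
        X <- X[, feats, drop = FALSE]
    } else if (ncol(X) != length(feats)) {
        stop("newdata has ", ncol(X), " columns; model expects ",
             length(feats))
    }
    X
}

#' Fit a logistic model tree
#'
#' Grows a decision tree by binary entropy splits while at least
#' `minSplit` training instances remain at a node; every node carries an
#' additive logistic model built by multiclass LogitBoost with simple
#' one-feature weighted-least-squares base learners, each child
#' warm-started from its parent's committee. The number of boosting
#' iterations per node is selected once at the root by stratified
#' `cvFolds`-fold cross-validation (earliest minimum of the pooled
#' validation error, with a no-improvement stop after `heuristicStop`
#' iterations), and the grown tree is pruned by CART cost-complexity
#' pruning with `cvFolds`-fold cross-validation. Deterministic given
#' `(x, y, seed)`.
#'
#' @param x a [FeatureMatrix-class], numeric matrix or data.frame.
#' @param y class labels (taken from `x` when it is a FeatureMatrix).
#' @param minSplit minimum node size eligible for splitting (default 15).
#' @param maxBoost maximum LogitBoost iterations considered (default 200).
#' @param cvFolds internal cross-validation folds (default 5).
#' @param heuristicStop patience of the iteration-selection stop
#'   (default 50).
#' @param prune logical, apply cost-complexity pruning (default TRUE).
#' @param maxDepth maximum tree depth; 0 forces a single boosted logistic
#'   model at the root.
#' @param seed integer seed for the internal cross-validations.
#' @return An [LMTModel-class].
#' @examples
#' d <- data.frame(a = c(rnorm(20), rnorm(20, 4)), b = rnorm(40))
#' fit <- fitLMT(d, rep(c("x", "y"), each = 20), seed = 1)
#' table(predict(fit, d))
#' @export
fitLMT <- function(x, y = NULL, minSplit = 15L, maxBoost = 200L,
                   cvFolds = 5L, heuristicStop = 50L, prune = TRUE,
                   maxDepth = Inf, seed = 1L) {
    xy <- .resolveXY(x, y)
    X <- xy$X; yf <- xy$y
    J <- nlevels(yf)
    spec <- list(minSplit = minSplit, maxBoost = maxBoost,
                 cvFolds = cvFolds, heuristicStop = heuristicStop,
                 prune = prune, maxDepth = maxDepth, seed = seed)
    if (J < 2L) {
        warning("only one class present; returning a constant model")
        root <- list(counts = length(yf), n = length(yf),
                     comm = list(feat = matrix(0L, 0, 1),
                                 a = matrix(0, 0, 1),
                                 b = matrix(0, 0, 1)),
                     err = 0L, leaf = TRUE)
        return(new("LMTModel", root = root, classes = levels(yf),
                   features = colnames(X) %||% sprintf("V%d", seq_len(ncol(X))),
                   iterations = 0L, spec = spec))
    }
    if (anyNA(X)) stop("missing values are not supported")
    yInt <- as.integer(yf)
    y01 <- matrix(0, nrow(X), J); y01[cbind(seq_len(nrow(X)), yInt)] <- 1
    iters <- .cvBoostIterations(X, y01, yInt, maxBoost, cvFolds,
                                heuristicStop,
                                .deriveSeed(seed, "lmt-iters"))
    root <- .growLMTNode(X, y01, yInt, matrix(0, nrow(X), J), iters,
                         minSplit, maxDepth, 0L)
    if (prune && !root$leaf) {
        nTotal <- nrow(X)
        seqFull <- .alphaSequence(root, nTotal)
        alphas <- seqFull$alphas
        cand <- c(0, sqrt(pmax(alphas, 0) *
                          c(alphas[-1L], max(alphas) * 4 + 1e-6)))
        cvFoldsP <- min(cvFolds, min(tabulate(yInt)))
        if (cvFoldsP >= 2L && length(cand) > 1L) {
            folds <- .withSeed(.deriveSeed(seed, "lmt-prune"), {
                idx <- unlist(lapply(seq_len(J), function(j)
                    sample(which(yInt == j))))
                split(idx, rep_len(seq_len(cvFoldsP), length(idx)))
            })
            cvErr <- numeric(length(cand))
            for (f in folds) {
                tr <- setdiff(seq_len(nTotal), f)
                ft <- .growLMTNode(X[tr, , drop = FALSE],
                                   y01[tr, , drop = FALSE], yInt[tr],
                                   matrix(0, length(tr), J), iters,
                                   minSplit, maxDepth, 0L)
                for (ci in seq_along(cand)) {
                    pt <- seqFull$collapse(ft, cand[ci])
                    Fv <- .lmtScores(pt, X[f, , drop = FALSE],
                                     matrix(0, length(f), J))
                    cvErr[ci] <- cvErr[ci] +
                        sum(max.col(Fv, ties.method = "first") != yInt[f])
                }
            }
            best <- max(which(cvErr == min(cvErr)))  # ties -> smaller tree
            if (cand[best] > 0)
                root <- seqFull$collapse(root, cand[best])
        }
    }
    new("LMTModel", root = root, classes = levels(yf),
        features = colnames(X) %||% sprintf("V%d", seq_len(ncol(X))),
        iterations = as.integer(iters), spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname predictProba
#' @export
setMethod("predictProba", "LMTModel", function(object, newdata) {
    X <- .resolveNewdata(object, newdata)
    J <- length(object@classes)
    if (J == 1L)
        return(matrix(1, nrow(X), 1L,
                      dimnames = list(NULL, object@classes)))
    F <- .lmtScores(object@root, X, matrix(0, nrow(X), J))
    P <- .softmax(F)
    colnames(P) <- object@classes
    P
})

#' @param object a fitted model.
#' @param newdata feature data with the training columns.
#' @describeIn fitLMT predicted class labels (argmax of the probabilities,
#'   ties to the earlier class).
#' @export
setMethod("predict", "LMTModel", function(object, newdata) {
    P <- predictProba(object, newdata)
    factor(object@classes[max.col(P, ties.method = "first")],
           levels = object@classes)
})
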