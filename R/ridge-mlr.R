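#' Fit multinomial logistic regression with a ridge estimator
#'
#' Maximises the multinomial log-likelihood minus `lambda * sum(coef^2)`
#' (intercepts unpenalised) under the reference-class parameterisation
#' (last class as reference) by Newton iterations with step halving,
#' stopping when the gradient's maximum absolute entry falls below `tol`.
#' The ridge penalty keeps the estimates finite and unique even on
#' separable data. Features are standardised internally to training mean 0
#' and sd 1; coefficients are reported on that internal scale.
#'
#' @param x a [FeatureMatrix-class], numeric matrix or data.frame.
#' @param y class labels (taken from `x` when it is a FeatureMatrix).
#' @param lambda ridge penalty, >= 0 (default 1e-8).
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxIter Newton iteration cap (default 200).
#' @return A [RidgeMLRModel-class].
#' @examples
#' d <- data.frame(a = c(rnorm(20), rnorm(20, 3)), b = rnorm(40))
#' fit <- fitRidgeMLR(d, rep(c("x", "y"), each = 20))
#' head(predictProba(fit, d))
#' @export
fitRidgeMLR <- function(x, y = NULL, lambda = 1e-8, tol = 1e-8,
                        maxIter = 200L) {
    if (lambda < 0) stop("'lambda' must be non-negative")
    xy <- .resolveXY(x, y)
    X <- xy$X; yf <- xy$y
    J <- nlevels(yf)
    if (J < 2L) stop("need at least 2 classes")
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- cbind(1, sweep(sweep(X, 2L, ctr), 2L, scl, "/"))
    n <- nrow(Xs); p <- ncol(Xs)        # p includes the intercept
    K <- J - 1L
    Y <- matrix(0, n, K)
    yInt <- as.integer(yf)
    sel <- yInt <= K
    Y[cbind(which(sel), yInt[sel])] <- 1
    pen <- rep(c(0, rep(1, p - 1L)), K)  # intercepts unpenalised
    beta <- numeric(p * K)
    objective <- function(beta) {
        B <- matrix(beta, p, K)
        Eta <- Xs %*% B
        m <- pmax(apply(Eta, 1L, max), 0)
        ll <- sum(Eta * Y) - sum(m + log(exp(-m) +
                                         rowSums(exp(Eta - m))))
        ll - lambda * sum(pen * beta^2)
    }
    obj <- objective(beta)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        B <- matrix(beta, p, K)
        Eta <- Xs %*% B
        m <- pmax(apply(Eta, 1L, max), 0)
        den <- exp(-m) + rowSums(exp(Eta - m))
        P <- exp(Eta - m) / den                  # n x K
        grad <- as.vector(crossprod(Xs, Y - P)) - 2 * lambda * pen * beta
        if (max(abs(grad)) < tol) { converged <- TRUE; break }
        H <- matrix(0, p * K, p * K)
        for (a in seq_len(K)) {
            ia <- ((a - 1L) * p + 1L):(a * p)
            for (b in a:K) {
                ib <- ((b - 1L) * p + 1L):(b * p)
                w <- if (a == b) P[, a] * (1 - P[, a])
                     else -P[, a] * P[, b]
                Hab <- crossprod(Xs, Xs * w)
                H[ia, ib] <- Hab
                if (a != b) H[ib, ia] <- Hab
            }
        }
        diag(H) <- diag(H) + 2 * lambda * pen + 1e-12
        step <- tryCatch(solve(H, grad), error = function(e)
            solve(H + diag(1e-6, nrow(H)), grad))
        fac <- 1
        repeat {
            cand <- beta + fac * step
            candObj <- objective(cand)
            if (is.finite(candObj) && candObj >= obj - 1e-12) break
            fac <- fac / 2
            if (fac < 1e-10) break
        }
        if (fac < 1e-10) break
        beta <- beta + fac * step
        obj <- objective(beta)
    }
    if (!converged && it >= maxIter) {
        cond <- simpleError(sprintf(
            "ridge MLR did not converge in %d iterations (|grad| = %.3g)",
            maxIter, max(abs(grad))))
        cond$beta <- matrix(beta, p, K)
        cond$gradient <- grad
        stop(cond)
    }
    new("RidgeMLRModel",
        coefficients = matrix(beta, p, K,
            dimnames = list(c("(Intercept)",
                              colnames(X) %||% sprintf("V%d", seq_len(p - 1L))),
                            levels(yf)[seq_len(K)])),
        lambda = lambda, center = ctr, scale = scl,
        classes = levels(yf),
        features = colnames(X) %||% sprintf("V%d", seq_len(p - 1L)),
        converged = converged, iterations = it)
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "RidgeMLRModel", function(object, newdata) {
    X <- .resolveNewdata(object, newdata)
    Xs <- cbind(1, sweep(sweep(X, 2L, object@center), 2L, object@scale,
                         "/"))
    Eta <- cbind(Xs %*% object@coefficients, 0)
    P <- .softmax(Eta)
    colnames(P) <- object@classes
    P
})

#' @param object a fitted model.
#' @param newdata feature data with the training columns.
#' @describeIn fitRidgeMLR predicted class labels.
#' @export
setMethod("predict", "RidgeMLRModel", function(object, newdata) {
    P <- predictProba(object, newdata)
    factor(object@classes[max.col(P, ties.method = "first")],
           levels = object@classes)
})
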