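#' Segment a recording into k contiguous parts
#'
#' Splits `T` time points into `k` non-overlapping contiguous segments:
#' the first `k - 1` of length `floor(T / k)`, the last absorbing the
#' remainder (so 4097 points at k = 4 give 1024/1024/1024/1025).
#'
#' @param nTotal total number of time points.
#' @param k number of segments (1 <= k <= nTotal).
#' @return integer matrix (k x 2) with columns `start`, `end`
#'   (1-based, inclusive).
#' @examples
#' b <- segmentBounds(4097, 4)
#' b[, 2] - b[, 1] + 1   # 1024 1024 1024 1025
#' @export
segmentBounds <- function(nTotal, k) {
    nTotal <- as.integer(nTotal); k <- as.integer(k)
    if (k < 1L || k > nTotal)
        stop("'k' must satisfy 1 <= k <= ", nTotal, ", got ", k)
    base <- nTotal %/% k
    len <- rep(base, k)
    len[k] <- nTotal - base * (k - 1L)
    end <- cumsum(len)
    cbind(start = c(1L, end[-k] + 1L), end = as.integer(end))
}

#' Unadjusted sample size for a proportion
#'
#' `n0 = z^2 p (1 - p) / d^2`: the sample size needed to estimate a
#' population proportion `p` within margin of error `d` at the confidence
#' level whose standard-normal variate is `z`. Returned unrounded.
#'
#' @param z standard normal variate of the confidence level (1.96 for 95%).
#' @param p assumed population proportion, in (0, 1); 0.5 is the
#'   conservative maximum.
#' @param d margin of error (desired precision), > 0.
#' @return numeric(1).
#' @examples
#' baseSampleSize(1.96, 0.5, 0.05)  # 384.16
#' @export
baseSampleSize <- function(z, p, d) {
    if (!is.finite(z) || z <= 0) stop("'z' must be positive")
    if (!is.finite(p) || p <= 0 || p >= 1)
        stop("'p' must lie strictly between 0 and 1")
    if (!is.finite(d) || d <= 0) stop("'d' must be positive")
    z^2 * p * (1 - p) / d^2
}

#' Finite-population-corrected sample size
#'
#' `n = n0 / (1 + (n0 - 1) / N)`, rounded to the nearest integer and
#' clamped to `[1, N]`. As `N` grows the correction vanishes and
#' `n -> round(n0)`.
#'
#' @param n0 unadjusted sample size from [baseSampleSize()].
#' @param N population size (time points in the class recording).
#' @return integer(1).
#' @examples
#' correctedSampleSize(384.16, 4097)  # 351
#' @export
correctedSampleSize <- function(n0, N) {
    if (!is.finite(n0) || n0 <= 0) stop("'n0' must be positive")
    N <- as.integer(N)
    if (N < 1L) stop("'N' must be at least 1")
    n <- round(n0 / (1 + (n0 - 1) / N))
    as.integer(max(1L, min(n, N)))
}

#' Sampling design for one class recording
#'
#' Bundles the design parameters with the derived sizes: `n0` from
#' [baseSampleSize()] and the finite-population-corrected total `n` from
#' [correctedSampleSize()].
#'
#' @param N population size (time points).
#' @param z,p,d design parameters; the default margin of error
#'   `d = 0.0076` is calibrated so that a 4097-point recording yields
#'   `n` close to 3288 (see the package vignette).
#' @return named list of class "SamplingDesign".
#' @export
samplingDesign <- function(N, z = 1.96, p = 0.5, d = 0.0076) {
    n0 <- baseSampleSize(z, p, d)
    n <- correctedSampleSize(n0, N)
    structure(list(z = z, p = p, d = d, N = as.integer(N),
                   n0 = n0, n = n),
              class = "SamplingDesign")
}

#' Per-segment, per-channel variances
#'
#' Computes the sample variance (divisor n - 1) of every channel within
#' every segment — the `S_ij^2` entering the optimum-allocation weights.
#'
#' @param rec an [EEGRecording-class].
#' @param bounds segment bounds from [segmentBounds()].
#' @return A [SegmentStats-class].
#' @export
computeSegmentStats <- function(rec, bounds) {
    m <- signalMatrix(rec)
    if (max(bounds) > nrow(m) || min(bounds) < 1L)
        stop("segment bounds exceed the recording")
    if (any(bounds[, 2L] - bounds[, 1L] < 1L))
        stop("every segment needs at least 2 time points for a variance")
    v <- t(apply(bounds, 1L, function(b)
        apply(m[b[1L]:b[2L], , drop = FALSE], 2L, stats::var)))
    if (ncol(m) == 1L) v <- matrix(v, ncol = 1L)
    colnames(v) <- colnames(m)
    new("SegmentStats", bounds = bounds, variances = v)
}

## largest-remainder rounding of nonneg reals to integers summing to n,
## respecting per-cell caps; ties go to the earlier segment
.largestRemainder <- function(target, n, caps) {
    al <- pmin(floor(target), caps)
    rem <- n - sum(al)
    while (rem > 0L) {
        frac <- target - floor(target)
        frac[al >= caps] <- -Inf
        if (all(!is.finite(frac))) {
            open <- which(al < caps)
            if (!length(open)) stop("total n exceeds the population")
            take <- open[seq_len(min(rem, length(open)))]
            al[take] <- al[take] + 1L
            rem <- n - sum(al)
            next
        }
        i <- which.max(frac)
        al[i] <- al[i] + 1L
        target[i] <- floor(target[i])  # consume its remainder
        rem <- rem - 1L
    }
    as.integer(al)
}

#' Optimum allocation of the total sample across segments
#'
#' Allocates the corrected total `n` across the k segments proportionally
#' to `w_i = N_i * sqrt(sum_j S_ij^2)` — segments with more within-segment
#' variability receive more of the sample. Real-valued shares are converted
#' to integers by the largest-remainder method so the allocations sum to
#' `n` exactly; allocations are capped at the segment length `N_i`, with
#' any excess redistributed proportionally over the uncapped segments.
#' When every weight is zero (all channels constant) the plan falls back
#' to allocation proportional to `N_i`, flagged in the result.
#'
#' @param n total sample size (integer, >= number of segments).
#' @param stats a [SegmentStats-class].
#' @return An [AllocationPlan-class].
#' @export
optimumAllocate <- function(n, stats) {
    n <- as.integer(n)
    Ni <- stats@bounds[, 2L] - stats@bounds[, 1L] + 1L
    k <- length(Ni)
    if (n < k) stop("'n' must be at least the number of segments")
    if (n > sum(Ni)) stop("'n' exceeds the number of available time points")
    w <- Ni * sqrt(rowSums(stats@variances))
    fallback <- FALSE
    if (sum(w) == 0) {
        w <- as.numeric(Ni)
        fallback <- TRUE
    }
    al <- rep(0L, k)
    caps <- as.integer(Ni)
    active <- rep(TRUE, k)
    nLeft <- n
    repeat {
        target <- w * 0
        wa <- if (sum(w[active]) > 0) w[active]
              else as.numeric(Ni[active])  # residual segments all flat
        target[active] <- wa / sum(wa) * nLeft
        over <- active & (target > caps - al)
        if (!any(over)) break
        al[over] <- caps[over]
        active[over] <- FALSE
        nLeft <- n - sum(al)
        if (!any(active) || nLeft <= 0L) break
    }
    if (nLeft > 0L && any(active)) {
        ai <- which(active)
        al[ai] <- .largestRemainder(target[ai], nLeft,
                                    caps[ai] - al[ai])
    }
    new("AllocationPlan", allocations = al, n = n,
        weights = Ni * sqrt(rowSums(stats@variances)),
        fallback = fallback)
}

#' Draw the OAT sample of one recording
#'
#' Within each segment, `n(i)` time indices are chosen by simple random
#' sampling without replacement and returned in ascending time order;
#' deterministic given `seed`.
#'
#' @param rec an [EEGRecording-class].
#' @param plan an [AllocationPlan-class] consistent with `bounds`.
#' @param bounds segment bounds from [segmentBounds()].
#' @param seed integer seed.
#' @return An [OATSample-class].
#' @export
drawOATSample <- function(rec, plan, bounds, seed = 1L) {
    m <- signalMatrix(rec)
    al <- plan@allocations
    if (nrow(bounds) != length(al))
        stop("plan and bounds disagree on the number of segments")
    Ni <- bounds[, 2L] - bounds[, 1L] + 1L
    if (any(al > Ni))
        stop("allocation exceeds segment length in segment(s) ",
             paste(which(al > Ni), collapse = ", "))
    rows <- .withSeed(seed, lapply(seq_along(al), function(i) {
        seg <- bounds[i, 1L]:bounds[i, 2L]
        sort(if (al[i] == Ni[i]) seg
             else seg[sample.int(Ni[i], al[i])])
    }))
    new("OATSample", setId = setId(rec), classLabel = classLabel(rec),
        rows = rows, data = m[unlist(rows), , drop = FALSE])
}

#' Combine OAT samples of several sets into one class sample
#'
#' Channel-wise concatenation of the selected rows: the first sample's
#' rows followed by the second's, and so on. All inputs must share the
#' channel count (channels are matched by position, set by set).
#'
#' @param samples list of [OATSample-class] objects.
#' @return An [OATSample-class] whose row count is the sum of the inputs'.
#' @export
combineOATSamples <- function(samples) {
    if (!length(samples)) stop("need at least one sample")
    if (length(samples) == 1L) return(samples[[1L]])
    nc <- vapply(samples, nChannels, integer(1))
    if (length(unique(nc)) > 1L)
        stop("channel-count mismatch across samples: ",
             paste(nc, collapse = ", "))
    cls <- unique(vapply(samples, classLabel, character(1)))
    dat <- do.call(rbind, lapply(samples, signalMatrix))
    colnames(dat) <- colnames(signalMatrix(samples[[1L]]))
    rows <- do.call(c, lapply(samples, selectedRows))
    new("OATSample",
        setId = paste(vapply(samples, setId, character(1)), collapse = "+"),
        classLabel = if (length(cls) == 1L) cls else cls[1L],
        rows = rows, data = dat)
}

#' One-call OAT sampling of a recording
#'
#' Convenience wrapper running design -> segmentation -> segment stats ->
#' allocation -> draw for a single recording.
#'
#' @param rec an [EEGRecording-class].
#' @param k number of segments (default 4).
#' @param z,p,d design parameters passed to [samplingDesign()].
#' @param seed integer seed for the draw.
#' @return list with elements `design`, `bounds`, `stats`, `plan`,
#'   `sample`.
#' @export
oatSampleSet <- function(rec, k = 4L, z = 1.96, p = 0.5, d = 0.0076,
                         seed = 1L) {
    des <- samplingDesign(nTimepoints(rec), z = z, p = p, d = d)
    bounds <- segmentBounds(nTimepoints(rec), k)
    st <- computeSegmentStats(rec, bounds)
    plan <- optimumAllocate(des$n, st)
    smp <- drawOATSample(rec, plan, bounds, seed = seed)
    list(design = des, bounds = bounds, stats = st, plan = plan,
         sample = smp)
}
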