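test_that("segmentation follows the floor rule with remainder in the last part", {
    lens <- function(b) b[, 2] - b[, 1] + 1
    expect_equal(lens(segmentBounds(4097, 4)), c(1024, 1024, 1024, 1025))
    expect_equal(lens(segmentBounds(100, 4)), c(25, 25, 25, 25))
    expect_equal(lens(segmentBounds(10, 3)), c(3, 3, 4))
    b <- segmentBounds(57, 5)
    expect_equal(unname(b[1, 1]), 1L)
    expect_equal(unname(b[5, 2]), 57L)
    expect_true(all(b[-1, 1] == b[-5, 2] + 1))  # contiguous cover
    expect_error(segmentBounds(3, 4), "k")
})

test_that("base sample size follows z^2 p (1-p) / d^2", {
    expect_equal(baseSampleSize(1.96, 0.5, 0.05), 384.16)
    expect_equal(baseSampleSize(2.576, 0.5, 0.02), 4147.36)
    # p = 0.5 maximises n0 for fixed z, d
    n0s <- vapply(seq(0.05, 0.95, by = 0.05),
                  function(p) baseSampleSize(1.96, p, 0.05), numeric(1))
    expect_equal(which.max(n0s), 10L)
    expect_error(baseSampleSize(1.96, 1.2, 0.05), "p")
    expect_error(baseSampleSize(1.96, 0.5, 0), "d")
})

test_that("finite-population correction rounds and clamps", {
    expect_equal(correctedSampleSize(384.16, 4097), 351L)
    expect_equal(correctedSampleSize(1, 50), 1L)
    expect_equal(correctedSampleSize(1, 1e6), 1L)
    # N -> infinity recovers round(n0)
    expect_equal(correctedSampleSize(384.16, 1e9), 384L)
    # never exceeds N
    expect_equal(correctedSampleSize(1e6, 100), 100L)
})

test_that("default design approximates the benchmark per-set total", {
    des <- samplingDesign(4097)
    expect_true(abs(des$n - 3288) <= 2)
})

test_that("segment variances are per-channel sample variances", {
    rec <- EEGRecording(matrix(c(1, 2, 3, 4, 7, 7, 7, 7), 4, 2),
                        setId = "A", durationSeconds = 1)
    st <- computeSegmentStats(rec, segmentBounds(4, 2))
    expect_equal(unname(st@variances[, 1]), c(0.5, 0.5))
    expect_equal(unname(st@variances[, 2]), c(0, 0))  # constant channel

    # scaling amplitudes by c scales variances by c^2
    rec2 <- EEGRecording(signalMatrix(rec) * 3, setId = "A",
                         durationSeconds = 1)
    st2 <- computeSegmentStats(rec2, segmentBounds(4, 2))
    expect_equal(st2@variances, 9 * st@variances)

    expect_error(computeSegmentStats(rec, segmentBounds(4, 4)),
                 "at least 2")
})

test_that("optimum allocation reproduces hand-computed shares", {
    st <- new("SegmentStats",
              bounds = cbind(start = c(1L, 501L), end = c(500L, 1000L)),
              variances = matrix(c(4, 16), 2, 1))
    plan <- optimumAllocate(100, st)
    expect_equal(allocations(plan), c(33L, 67L))  # weights 1000 : 2000
    expect_equal(plan@weights, c(1000, 2000))
    expect_false(plan@fallback)

    # symmetry: equal sizes and variances split evenly
    st4 <- new("SegmentStats",
               bounds = cbind(start = c(1L, 26L, 51L, 76L),
                              end = c(25L, 50L, 75L, 100L)),
               variances = matrix(2, 4, 3))
    expect_equal(allocations(optimumAllocate(100, st4)), rep(25L, 4))
})

test_that("allocation conserves the total and caps at segment sizes", {
    for (seed in 1:200) {
        set.seed(seed)
        k <- sample(2:6, 1)
        Ni <- sample(5:60, k, replace = TRUE)
        ends <- cumsum(Ni)
        st <- new("SegmentStats",
                  bounds = cbind(start = c(1L, ends[-k] + 1L),
                                 end = as.integer(ends)),
                  variances = matrix(rexp(k * 3), k, 3))
        n <- sample(k:sum(Ni), 1)
        al <- allocations(optimumAllocate(n, st))
        expect_identical(sum(al), n)
        expect_true(all(al <= Ni))
        expect_true(all(al >= 0))
    }
})

test_that("zero-variance recordings fall back to proportional allocation", {
    st <- new("SegmentStats",
              bounds = cbind(start = c(1L, 11L), end = c(10L, 40L)),
              variances = matrix(0, 2, 2))
    plan <- optimumAllocate(20, st)
    expect_true(plan@fallback)
    expect_equal(allocations(plan), c(5L, 15L))  # proportional to 10:30
})

test_that("raising a segment's variability never lowers its share", {
    base <- matrix(c(1, 1, 1), 3, 1)
    shares <- vapply(c(1, 2, 5, 20, 100), function(v) {
        st <- new("SegmentStats",
                  bounds = cbind(start = c(1L, 41L, 81L),
                                 end = c(40L, 80L, 120L)),
                  variances = matrix(c(v, 1, 1), 3, 1))
        w <- st@bounds[, 2] - st@bounds[, 1] + 1
        wts <- w * sqrt(st@variances[, 1])
        wts[1] / sum(wts)
    }, numeric(1))
    expect_true(all(diff(shares) > 0))
})

test_that("draws honour the plan, the seed and the segment boundaries", {
    rec <- tinyRecording(nT = 40, nCh = 3)
    bounds <- segmentBounds(40, 4)
    st <- computeSegmentStats(rec, bounds)
    plan <- optimumAllocate(20, st)
    s1 <- drawOATSample(rec, plan, bounds, seed = 11)
    s2 <- drawOATSample(rec, plan, bounds, seed = 11)
    expect_identical(selectedRows(s1), selectedRows(s2))
    expect_equal(lengths(selectedRows(s1)), allocations(plan))
    for (i in seq_len(nrow(bounds))) {
        r <- selectedRows(s1)[[i]]
        expect_true(all(r >= bounds[i, 1] & r <= bounds[i, 2]))
        expect_false(is.unsorted(r, strictly = TRUE))
    }
    expect_equal(nrow(signalMatrix(s1)), 20)
})

test_that("exhaustive sampling reproduces the recording and its features", {
    rec <- tinyRecording(nT = 36, nCh = 2)
    bounds <- segmentBounds(36, 3)
    st <- computeSegmentStats(rec, bounds)
    plan <- optimumAllocate(36, st)  # n = N forces full allocation
    expect_equal(allocations(plan), rep(12L, 3))
    s <- drawOATSample(rec, plan, bounds, seed = 1)
    expect_equal(signalMatrix(s), signalMatrix(rec))
    expect_identical(featureValues(featuresPerClass(s)),
                     featureValues(featuresPerClass(rec)))
})

test_that("within a segment every row is drawn uniformly", {
    rec <- tinyRecording(nT = 30, nCh = 1)
    bounds <- segmentBounds(30, 2)
    plan <- new("AllocationPlan", allocations = c(5L, 10L), n = 15L,
                weights = c(1, 1), fallback = FALSE)
    nRep <- 600
    hits <- numeric(30)
    for (sd in seq_len(nRep)) {
        s <- drawOATSample(rec, plan, bounds, seed = sd)
        hits[unlist(selectedRows(s))] <- hits[unlist(selectedRows(s))] + 1
    }
    freq <- hits / nRep
    for (i in 1:2) {
        pExp <- plan@allocations[i] /
            (bounds[i, 2] - bounds[i, 1] + 1)
        se <- sqrt(pExp * (1 - pExp) / nRep)
        rows <- bounds[i, 1]:bounds[i, 2]
        expect_true(all(abs(freq[rows] - pExp) <= 3 * se + 1e-9))
    }
})

test_that("combining samples concatenates rows channel-wise", {
    rec <- tinyRecording(nT = 40, nCh = 2)
    bounds <- segmentBounds(40, 2)
    st <- computeSegmentStats(rec, bounds)
    a <- drawOATSample(rec, optimumAllocate(12, st), bounds, seed = 1)
    b <- drawOATSample(rec, optimumAllocate(9, st), bounds, seed = 2)
    comb <- combineOATSamples(list(a, b))
    expect_equal(nrow(signalMatrix(comb)), 21)
    expect_equal(signalMatrix(comb),
                 rbind(signalMatrix(a), signalMatrix(b)))
    expect_equal(setId(comb), "A+A")

    # identity on a single input
    expect_identical(combineOATSamples(list(a)), a)

    bad <- drawOATSample(tinyRecording(nT = 40, nCh = 3),
                         optimumAllocate(12, computeSegmentStats(
                             tinyRecording(nT = 40, nCh = 3), bounds)),
                         bounds, seed = 1)
    expect_error(combineOATSamples(list(a, bad)), "mismatch")
})
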