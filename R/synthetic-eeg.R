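#' Class profile for the synthetic EEG generator
#'
#' Parameters of one diagnostic class of the benchmark-shaped generator.
#' A channel is simulated as second-order autoregressive (AR(2)) noise plus
#' a sinusoidal rhythm plus Poisson-timed spike bursts, the sum scaled by
#' `amplitudeScale` (jittered mildly per channel to mimic inter-channel
#' variation).
#'
#' @param classLabel one of [classLevels()].
#' @param arCoefficients length-2 numeric, AR(2) coefficients; must lie in
#'   the stationarity triangle (|a2| < 1, a2 + a1 < 1, a2 - a1 < 1).
#' @param noiseSd innovation standard deviation, microvolts.
#' @param oscillationFrequency rhythm frequency, Hz.
#' @param oscillationAmplitude rhythm amplitude, microvolts.
#' @param burstRate spike-burst rate, events per second.
#' @param burstAmplitude spike peak amplitude, microvolts.
#' @param amplitudeScale overall multiplicative scale.
#' @param channelJitterSd sd of the per-channel log-normal scale jitter.
#' @return named list of class "ClassProfile".
#' @export
classProfile <- function(classLabel, arCoefficients = c(1.2, -0.5),
                         noiseSd = 10, oscillationFrequency = 10,
                         oscillationAmplitude = 0, burstRate = 0,
                         burstAmplitude = 0, amplitudeScale = 1,
                         channelJitterSd = 0.15) {
    a <- arCoefficients
    if (length(a) != 2L || any(!is.finite(a)) ||
        abs(a[2L]) >= 1 || a[1L] + a[2L] >= 1 || a[2L] - a[1L] >= 1)
        stop("AR coefficients outside the stationarity region")
    if (noiseSd <= 0) stop("'noiseSd' must be positive")
    if (oscillationAmplitude < 0 || burstAmplitude < 0 ||
        amplitudeScale < 0 || burstRate < 0)
        stop("amplitudes and rates must be non-negative")
    structure(list(classLabel = classLabel, arCoefficients = a,
                   noiseSd = noiseSd,
                   oscillationFrequency = oscillationFrequency,
                   oscillationAmplitude = oscillationAmplitude,
                   burstRate = burstRate, burstAmplitude = burstAmplitude,
                   amplitudeScale = amplitudeScale,
                   channelJitterSd = channelJitterSd),
              class = "ClassProfile")
}

#' Default class profiles of the synthetic benchmark
#'
#' Healthy: moderate alpha-band (10 Hz) rhythm over AR(2) background.
#' Seizure-free (interictal): heavier background with sparse low-rate
#' spikes, giving elevated tails (kurtosis/skewness) without the seizure
#' class's amplitude. Seizure (ictal): large-amplitude rhythmic 3 Hz
#' activity, around an order of magnitude above the healthy scale.
#'
#' @return named list of three "ClassProfile" objects.
#' @export
defaultClassProfiles <- function() {
    list(
        "healthy" = classProfile("healthy",
            arCoefficients = c(1.2, -0.5), noiseSd = 10,
            oscillationFrequency = 10, oscillationAmplitude = 20,
            burstRate = 0, burstAmplitude = 0, amplitudeScale = 1),
        "seizure-free" = classProfile("seizure-free",
            arCoefficients = c(1.3, -0.6), noiseSd = 14,
            oscillationFrequency = 6, oscillationAmplitude = 10,
            burstRate = 0.6, burstAmplitude = 150, amplitudeScale = 1),
        "seizure" = classProfile("seizure",
            arCoefficients = c(1.2, -0.5), noiseSd = 40,
            oscillationFrequency = 3, oscillationAmplitude = 300,
            burstRate = 2, burstAmplitude = 200, amplitudeScale = 1)
    )
}

## stationary variance of an AR(2) process with innovation sd sigma
.ar2StationaryVariance <- function(a1, a2, sigma) {
    sigma^2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

#' Generate one synthetic EEG channel
#'
#' Deterministic given `(profile, nPoints, samplingRate, seed)`: AR(2)
#' noise (warmed up past its transient), a sinusoid at the profile's rhythm
#' frequency with random phase, and Poisson-timed double-exponential spike
#' bursts; the sum is multiplied by the profile's amplitude scale times a
#' per-channel log-normal jitter.
#'
#' @param profile a [classProfile()].
#' @param nPoints number of samples (> 0).
#' @param samplingRate sampling rate in Hz.
#' @param seed integer seed for this channel's RNG stream.
#' @return numeric vector of length `nPoints` (microvolts).
#' @export
generateChannel <- function(profile, nPoints, samplingRate = 4097 / 23.6,
                            seed = 1L) {
    stopifnot(inherits(profile, "ClassProfile"), nPoints > 0)
    .withSeed(seed, {
        a <- profile$arCoefficients
        burn <- 200L
        innov <- stats::rnorm(nPoints + burn, sd = profile$noiseSd)
        x <- stats::filter(innov, a, method = "recursive")
        x <- as.numeric(x)[(burn + 1L):(burn + nPoints)]
        tt <- (seq_len(nPoints) - 1L) / samplingRate
        if (profile$oscillationAmplitude > 0) {
            phase <- stats::runif(1, 0, 2 * pi)
            x <- x + profile$oscillationAmplitude *
                sin(2 * pi * profile$oscillationFrequency * tt + phase)
        }
        if (profile$burstRate > 0 && profile$burstAmplitude > 0) {
            dur <- nPoints / samplingRate
            nEv <- stats::rpois(1, profile$burstRate * dur)
            if (nEv > 0) {
                centers <- stats::runif(nEv, 0, dur)
                signs <- sample(c(-1, 1), nEv, replace = TRUE)
                width <- 0.02  # ~20 ms spikes
                for (e in seq_len(nEv))
                    x <- x + signs[e] * profile$burstAmplitude *
                        exp(-abs(tt - centers[e]) / width)
            }
        }
        jit <- exp(stats::rnorm(1, 0, profile$channelJitterSd))
        x * profile$amplitudeScale * jit
    })
}

#' Generate a benchmark-shaped five-set synthetic dataset
#'
#' Emulates the shape of the public epileptic-EEG benchmark: five sets of
#' `nChannels` single-channel recordings of `nPoints` samples
#' (`durationSeconds` long); sets A and B draw from the healthy profile,
#' C and D from the seizure-free profile, E from the seizure profile.
#' Each channel has its own RNG stream derived from
#' `(seed, setId, channel index)`, so the output is a pure function of the
#' arguments.
#'
#' @param seed integer base seed.
#' @param profiles named list of class profiles as from
#'   [defaultClassProfiles()].
#' @param nChannels channels per set (benchmark: 100).
#' @param nPoints samples per channel (benchmark: 4097).
#' @param durationSeconds duration per channel (benchmark: 23.6 s).
#' @return named list of five [EEGRecording-class] objects (A..E).
#' @examples
#' sets <- generateBenchmarkDataset(seed = 1, nChannels = 3, nPoints = 64)
#' sets$E
#' @export
generateBenchmarkDataset <- function(seed = 1L,
                                     profiles = defaultClassProfiles(),
                                     nChannels = 100L, nPoints = 4097L,
                                     durationSeconds = 23.6) {
    setClass <- .SET_CLASS_MAP
    rate <- nPoints / durationSeconds
    out <- lapply(names(setClass), function(sid) {
        prof <- profiles[[setClass[[sid]]]]
        m <- vapply(seq_len(nChannels), function(j)
            generateChannel(prof, nPoints, rate,
                            seed = .deriveSeed(seed, sid, j)),
            numeric(nPoints))
        colnames(m) <- sprintf("%s%03d", sid, seq_len(nChannels))
        EEGRecording(m, setId = sid, durationSeconds = durationSeconds)
    })
    names(out) <- names(setClass)
    out
}
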