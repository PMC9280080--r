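## S4 classes for the signal, spectral and controller layers.

#' SignalTrace: a uniformly sampled multi-channel voltage series
#'
#' The basic container for raw sEMG.  Samples are stored as a numeric matrix
#' with one column per channel, in millivolts.  The sampling rate and an
#' absolute start time complete the time axis: sample \code{i} (1-based) sits
#' at \code{t0 + (i - 1) / fs} seconds.
#'
#' @slot samples numeric matrix, \code{n} samples x \code{k} channels (mV).
#' @slot fs sampling rate in Hz (> 0).
#' @slot channelNames character vector of channel labels, one per column.
#' @slot t0 start time of the first sample, seconds.
#'
#' @seealso \code{\link{signalTrace}}, \code{\link{readTrace}}
#' @exportClass SignalTrace
setClass("SignalTrace",
  representation(samples = "matrix", fs = "numeric",
                 channelNames = "character", t0 = "numeric"),
  prototype(samples = matrix(0, 1, 1), fs = 1100,
            channelNames = "ch1", t0 = 0))

setValidity("SignalTrace", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (nrow(object@samples) < 1L) msg <- c(msg, "trace must hold at least one sample")
  if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelNames) != ncol(object@samples))
    msg <- c(msg, "one channel name per column required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' WindowSpec: a sliding analysis window
#'
#' @slot lengthSamples window length in samples.
#' @slot hopSamples stride between window starts in samples.
#' @slot taper name of the taper shape: "hann", "hamming" or "rectangular".
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(lengthSamples = "integer", hopSamples = "integer",
                 taper = "character"),
  prototype(lengthSamples = 256L, hopSamples = 64L, taper = "hann"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@lengthSamples < 1L) msg <- c(msg, "lengthSamples must be positive")
  if (object@hopSamples < 1L) msg <- c(msg, "hopSamples must be positive")
  if (object@hopSamples > object@lengthSamples)
    msg <- c(msg, "hopSamples must not exceed lengthSamples")
  if (!object@taper %in% c("hann", "hamming", "rectangular"))
    msg <- c(msg, "taper must be one of 'hann', 'hamming', 'rectangular'")
  if (length(msg)) msg else TRUE
})

#' PowerSpectrum: a one-sided spectrum of a single window
#'
#' Holds either a power spectral density (\code{kind = "psd"}, mV^2/Hz) or a
#' linear amplitude spectrum (\code{kind = "magnitude"}, mV) on strictly
#' increasing non-negative bin centre frequencies.
#'
#' @slot freqs bin centre frequencies (Hz).
#' @slot values per-bin PSD or magnitude values (>= 0).
#' @slot kind "psd" or "magnitude".
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  representation(freqs = "numeric", values = "numeric", kind = "character"),
  prototype(freqs = numeric(), values = numeric(), kind = "psd"))

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@values))
    msg <- c(msg, "freqs and values must have equal length")
  if (length(object@freqs) && (any(object@freqs < 0) || any(diff(object@freqs) <= 0)))
    msg <- c(msg, "freqs must be non-negative and strictly increasing")
  if (any(object@values < 0)) msg <- c(msg, "spectral values must be non-negative")
  if (!object@kind %in% c("psd", "magnitude"))
    msg <- c(msg, "kind must be 'psd' or 'magnitude'")
  if (length(msg)) msg else TRUE
})

#' FeatureSeries: time-indexed scalar feature values for one channel
#'
#' @slot times frame timestamps in seconds, strictly increasing.  A frame is
#'   stamped with the time of its \emph{last} sample (causal convention).
#' @slot values feature values.
#' @slot feature one of "RIEMG", "RMS", "FMED", "FMEAN", "BANDMAG".
#' @slot channel channel label.
#' @slot units "mV" or "Hz".
#' @exportClass FeatureSeries
setClass("FeatureSeries",
  representation(times = "numeric", values = "numeric",
                 feature = "character", channel = "character",
                 units = "character"),
  prototype(times = numeric(), values = numeric(),
            feature = "RMS", channel = "ch1", units = "mV"))

setValidity("FeatureSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (!object@feature %in% c("RIEMG", "RMS", "FMED", "FMEAN", "BANDMAG"))
    msg <- c(msg, "unknown feature name")
  if (object@feature %in% c("RIEMG", "RMS", "BANDMAG") &&
      length(object@values) && any(object@values < 0))
    msg <- c(msg, "amplitude features must be non-negative")
  if (length(msg)) msg else TRUE
})

#' STFTConfig: short-time Fourier transform parameters
#'
#' Defaults replicate the embedded pipeline: a 256-point FFT on a 1100 Hz
#' stream with a 64-sample hop and a Hann taper.
#'
#' @slot fftLen FFT length in samples, a power of two.
#' @slot hop hop between frames in samples (<= fftLen).
#' @slot fs sampling rate in Hz.
#' @slot taper taper shape applied before the FFT.
#' @exportClass STFTConfig
setClass("STFTConfig",
  representation(fftLen = "integer", hop = "integer", fs = "numeric",
                 taper = "character"),
  prototype(fftLen = 256L, hop = 64L, fs = 1100, taper = "hann"))

setValidity("STFTConfig", function(object) {
  msg <- character()
  L <- object@fftLen
  if (L < 2L || bitwAnd(L, L - 1L) != 0L)
    msg <- c(msg, "fftLen must be a power of two >= 2")
  if (object@hop < 1L || object@hop > L)
    msg <- c(msg, "hop must be in [1, fftLen]")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@taper %in% c("hann", "hamming", "rectangular"))
    msg <- c(msg, "taper must be one of 'hann', 'hamming', 'rectangular'")
  if (length(msg)) msg else TRUE
})

#' Spectrogram: time-ordered one-sided magnitude frames per channel
#'
#' Magnitudes are amplitude-normalised so that an on-bin unit sinusoid reads
#' approximately 1 mV in its bin; frame timestamps carry the time of each
#' frame's last sample.
#'
#' @slot freqs bin centre frequencies (Hz), length fftLen/2 + 1.
#' @slot times frame timestamps (s), strictly increasing with constant stride.
#' @slot magnitudes named list, one bins x frames matrix per channel.
#' @slot channelNames channel labels.
#' @slot config the \code{STFTConfig} used.
#' @exportClass Spectrogram
setClass("Spectrogram",
  representation(freqs = "numeric", times = "numeric", magnitudes = "list",
                 channelNames = "character", config = "STFTConfig"))

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (length(object@magnitudes) != length(object@channelNames))
    msg <- c(msg, "one magnitude matrix per channel required")
  for (m in object@magnitudes) {
    if (!is.matrix(m) || nrow(m) != length(object@freqs))
      msg <- c(msg, "each magnitude matrix needs one row per frequency bin")
    if (is.matrix(m) && ncol(m) != length(object@times))
      msg <- c(msg, "each magnitude matrix needs one column per frame")
    if (length(m) && any(m < 0)) msg <- c(msg, "magnitudes must be non-negative")
  }
  if (length(object@times) > 1L) {
    strides <- diff(object@times)
    if (any(strides <= 0) || diff(range(strides)) > 1e-9)
      msg <- c(msg, "frame times must increase with a constant stride")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' SubjectProfile: per-subject generative parameters for synthetic sEMG
#'
#' @slot gains named multiplicative amplitude factors, one per channel
#'   (dimensionless, > 0).
#' @slot spectralPeakHz carrier peak frequency in Hz (30-200).
#' @slot restNoiseMv resting baseline RMS in mV.
#' @slot contractionMv nominal contraction RMS in mV (> restNoiseMv).
#' @slot bandGain fraction (0-1) of carrier amplitude carried by the
#'   narrowband resonant component; the remainder is spread over the
#'   out-of-band 30-55 / 90-200 Hz portions of the contraction spectrum.
#' @slot seed integer RNG seed; one seed fully determines an episode.
#' @exportClass SubjectProfile
setClass("SubjectProfile",
  representation(gains = "numeric", spectralPeakHz = "numeric",
                 restNoiseMv = "numeric", contractionMv = "numeric",
                 bandGain = "numeric", seed = "integer"),
  prototype(gains = c(flexor = 1, extensor = 1), spectralPeakHz = 70,
            restNoiseMv = 20, contractionMv = 400, bandGain = 0.85,
            seed = 0L))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (any(object@gains <= 0)) msg <- c(msg, "gains must be positive")
  if (is.null(names(object@gains)) || anyDuplicated(names(object@gains)))
    msg <- c(msg, "gains must carry unique channel names")
  if (object@spectralPeakHz < 30 || object@spectralPeakHz > 200)
    msg <- c(msg, "spectralPeakHz must lie in [30, 200]")
  if (object@restNoiseMv < 0) msg <- c(msg, "restNoiseMv must be >= 0")
  if (object@restNoiseMv >= object@contractionMv)
    msg <- c(msg, "restNoiseMv must be below contractionMv")
  if (object@bandGain <= 0 || object@bandGain > 1)
    msg <- c(msg, "bandGain must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ArtifactSpec: additive contamination of the recorded signal
#'
#' Powerline interference is a pure sinusoid; the motion artifact is
#' low-frequency noise confined below \code{motionCutoffHz}; broadband noise
#' is white.  All amplitudes may be zero (clean recording).
#'
#' @slot powerlineHz mains frequency, 50 or 60 Hz.
#' @slot powerlineAmpMv peak amplitude of the mains sinusoid (mV).
#' @slot motionCutoffHz upper edge of the motion artifact band (Hz).
#' @slot motionAmpMv RMS of the motion artifact (mV).
#' @slot broadbandNoiseMv RMS of additive white noise (mV).
#' @exportClass ArtifactSpec
setClass("ArtifactSpec",
  representation(powerlineHz = "numeric", powerlineAmpMv = "numeric",
                 motionCutoffHz = "numeric", motionAmpMv = "numeric",
                 broadbandNoiseMv = "numeric"),
  prototype(powerlineHz = 50, powerlineAmpMv = 0, motionCutoffHz = 20,
            motionAmpMv = 0, broadbandNoiseMv = 0))

setValidity("ArtifactSpec", function(object) {
  msg <- character()
  if (!object@powerlineHz %in% c(50, 60))
    msg <- c(msg, "powerlineHz must be 50 or 60")
  amps <- c(object@powerlineAmpMv, object@motionAmpMv, object@broadbandNoiseMv)
  if (any(amps < 0)) msg <- c(msg, "artifact amplitudes must be >= 0")
  if (object@motionCutoffHz <= 0) msg <- c(msg, "motionCutoffHz must be positive")
  if (length(msg)) msg else TRUE
})

#' TriggerConfig: thresholding and state-machine parameters
#'
#' @slot mode "STFT_BAND" (60-80 Hz band magnitude) or "RMS" (broadband
#'   amplitude baseline).
#' @slot band lower and upper band edges in Hz (STFT_BAND mode).
#' @slot thresholdFraction fraction of the calibration maximum used as the
#'   triggering threshold (the 50 percent rule).
#' @slot thresholds calibrated per-channel thresholds in mV (named; empty
#'   before calibration).
#' @slot debounceFrames number of consecutive agreeing frames required
#'   before a state change is committed (>= 1).
#' @slot releaseFraction hysteresis multiplier (<= 1): an active state
#'   persists until its channel falls below releaseFraction * threshold.
#' @slot smoothFrames length of the causal (trailing) moving average applied
#'   to the per-frame feature before thresholding, in frames (>= 1; 1
#'   disables smoothing).  Both the calibration series and the runtime
#'   series are smoothed identically.
#' @exportClass TriggerConfig
setClass("TriggerConfig",
  representation(mode = "character", band = "numeric",
                 thresholdFraction = "numeric", thresholds = "numeric",
                 debounceFrames = "integer", releaseFraction = "numeric",
                 smoothFrames = "integer"),
  prototype(mode = "STFT_BAND", band = c(60, 80), thresholdFraction = 0.5,
            thresholds = numeric(), debounceFrames = 1L,
            releaseFraction = 0.6, smoothFrames = 3L))

setValidity("TriggerConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("STFT_BAND", "RMS"))
    msg <- c(msg, "mode must be 'STFT_BAND' or 'RMS'")
  if (length(object@band) != 2L || object@band[1] >= object@band[2] ||
      any(object@band < 0))
    msg <- c(msg, "band must be (lo, hi) with 0 <= lo < hi")
  if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1)
    msg <- c(msg, "thresholdFraction must lie in (0, 1)")
  if (length(object@thresholds)) {
    if (any(object@thresholds <= 0))
      msg <- c(msg, "calibrated thresholds must be positive")
    if (is.null(names(object@thresholds)))
      msg <- c(msg, "thresholds must be named by channel")
  }
  if (object@debounceFrames < 1L) msg <- c(msg, "debounceFrames must be >= 1")
  if (object@releaseFraction <= 0 || object@releaseFraction > 1)
    msg <- c(msg, "releaseFraction must lie in (0, 1]")
  if (object@smoothFrames < 1L) msg <- c(msg, "smoothFrames must be >= 1")
  if (length(msg)) msg else TRUE
})
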