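## Constructors, accessors and show methods.

#' Construct a SignalTrace
#'
#' @param samples numeric vector (single channel) or matrix with one column
#'   per channel, in mV.
#' @param fs sampling rate in Hz.
#' @param channelNames labels, one per channel; defaults to column names or
#'   \code{ch1, ch2, ...}.
#' @param t0 start time of the first sample in seconds.
#' @return a validated \code{\link{SignalTrace}}.
#' @examples
#' tr <- signalTrace(cbind(flexor = rnorm(100), extensor = rnorm(100)), fs = 1100)
#' nSamples(tr)
#' @export
signalTrace <- function(samples, fs, channelNames = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(channelNames)) {
    channelNames <- colnames(samples)
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(ncol(samples)))
  }
  colnames(samples) <- channelNames
  new("SignalTrace", samples = samples, fs = as.numeric(fs),
      channelNames = as.character(channelNames), t0 = as.numeric(t0))
}

#' Construct a WindowSpec
#' @param lengthSamples window length in samples.
#' @param hopSamples stride between consecutive windows in samples.
#' @param taper taper name: "hann", "hamming" or "rectangular".
#' @return a validated \code{\link{WindowSpec}}.
#' @export
windowSpec <- function(lengthSamples = 256L, hopSamples = 64L, taper = "hann") {
  new("WindowSpec", lengthSamples = as.integer(lengthSamples),
      hopSamples = as.integer(hopSamples), taper = taper)
}

#' Construct a PowerSpectrum
#' @param freqs bin centre frequencies in Hz, strictly increasing.
#' @param values per-bin values (PSD in mV^2/Hz or magnitude in mV).
#' @param kind "psd" or "magnitude".
#' @return a validated \code{\link{PowerSpectrum}}.
#' @export
powerSpectrum <- function(freqs, values, kind = c("psd", "magnitude")) {
  new("PowerSpectrum", freqs = as.numeric(freqs), values = as.numeric(values),
      kind = match.arg(kind))
}

#' Construct a FeatureSeries
#' @param times frame timestamps in seconds.
#' @param values feature values.
#' @param feature feature name.
#' @param channel channel label.
#' @param units "mV" or "Hz".
#' @return a validated \code{\link{FeatureSeries}}.
#' @export
featureSeries <- function(times, values,
                          feature = c("RMS", "RIEMG", "FMED", "FMEAN", "BANDMAG"),
                          channel = "ch1", units = NULL) {
  feature <- match.arg(feature)
  if (is.null(units))
    units <- if (feature %in% c("FMED", "FMEAN")) "Hz" else "mV"
  new("FeatureSeries", times = as.numeric(times), values = as.numeric(values),
      feature = feature, channel = channel, units = units)
}

#' Construct an STFTConfig
#' @param fftLen FFT length (power of two); default 256 as in the embedded
#'   pipeline.
#' @param hop hop size in samples; 64 keeps frame latency under the 300 ms
#'   recognition budget.
#' @param fs sampling rate in Hz; default 1100 (the embedded ADC rate).
#' @param taper analysis taper; Hann by default to bound leakage of mains
#'   interference into the 60-80 Hz band.
#' @return a validated \code{\link{STFTConfig}}.
#' @export
stftConfig <- function(fftLen = 256L, hop = 64L, fs = 1100, taper = "hann") {
  new("STFTConfig", fftLen = as.integer(fftLen), hop = as.integer(hop),
      fs = as.numeric(fs), taper = taper)
}

#' Construct a SubjectProfile
#'
#' Defaults describe a nominal subject: contraction bursts at 400 mV RMS with
#' spectral peak at 70 Hz, a 20 mV resting baseline, and unit amplitude gains
#' on both channels.
#'
#' @param gains named positive amplitude factors per channel.
#' @param spectralPeakHz carrier peak frequency (Hz).
#' @param restNoiseMv resting baseline RMS (mV).
#' @param contractionMv nominal contraction RMS (mV).
#' @param bandGain fraction of carrier amplitude in the narrowband resonant
#'   component (see \code{\link{SubjectProfile}}).
#' @param seed integer seed; fully determines any episode generated from
#'   this profile.
#' @return a validated \code{\link{SubjectProfile}}.
#' @export
subjectProfile <- function(gains = c(flexor = 1, extensor = 1),
                           spectralPeakHz = 70, restNoiseMv = 20,
                           contractionMv = 400, bandGain = 0.85, seed = 0L) {
  new("SubjectProfile", gains = gains, spectralPeakHz = spectralPeakHz,
      restNoiseMv = restNoiseMv, contractionMv = contractionMv,
      bandGain = bandGain, seed = as.integer(seed))
}

#' Construct an ArtifactSpec
#' @param powerlineHz mains frequency (50 or 60 Hz).
#' @param powerlineAmpMv peak amplitude of the mains sinusoid (mV).
#' @param motionCutoffHz upper edge of the motion artifact band (Hz).
#' @param motionAmpMv RMS of the low-frequency motion artifact (mV).
#' @param broadbandNoiseMv RMS of additive white noise (mV).
#' @return a validated \code{\link{ArtifactSpec}}.
#' @export
artifactSpec <- function(powerlineHz = 50, powerlineAmpMv = 0,
                         motionCutoffHz = 20, motionAmpMv = 0,
                         broadbandNoiseMv = 0) {
  new("ArtifactSpec", powerlineHz = powerlineHz,
      powerlineAmpMv = powerlineAmpMv, motionCutoffHz = motionCutoffHz,
      motionAmpMv = motionAmpMv, broadbandNoiseMv = broadbandNoiseMv)
}

#' Construct a TriggerConfig
#' @param mode "STFT_BAND" or "RMS".
#' @param band band edges in Hz for STFT_BAND mode.
#' @param thresholdFraction fraction of the calibration maximum (0.5: the
#'   50 percent rule).
#' @param thresholds named per-channel thresholds in mV; normally filled in
#'   by \code{\link{calibrateTrigger}}.
#' @param debounceFrames consecutive agreeing frames required for a state
#'   change.
#' @param releaseFraction hysteresis release multiplier.
#' @param smoothFrames trailing moving-average length (frames) applied to
#'   the feature series before thresholding; 1 disables smoothing.
#' @return a validated \code{\link{TriggerConfig}}.
#' @export
triggerConfig <- function(mode = c("STFT_BAND", "RMS"), band = c(60, 80),
                          thresholdFraction = 0.5, thresholds = numeric(),
                          debounceFrames = 1L, releaseFraction = 0.6,
                          smoothFrames = 3L) {
  new("TriggerConfig", mode = match.arg(mode), band = as.numeric(band),
      thresholdFraction = thresholdFraction, thresholds = thresholds,
      debounceFrames = as.integer(debounceFrames),
      releaseFraction = releaseFraction,
      smoothFrames = as.integer(smoothFrames))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn signalTrace number of samples per channel.
#' @param trace a \code{SignalTrace}.
#' @export
nSamples <- function(trace) nrow(trace@samples)

#' @describeIn signalTrace sampling rate in Hz.
#' @export
sampleRate <- function(trace) trace@fs

#' @describeIn signalTrace channel labels.
#' @export
channelNames <- function(trace) trace@channelNames

#' @describeIn signalTrace sample matrix (n x channels, mV).
#' @export
traceSamples <- function(trace) trace@samples

#' @describeIn signalTrace duration in seconds (\code{n / fs}).
#' @export
traceDuration <- function(trace) nrow(trace@samples) / trace@fs

#' @describeIn signalTrace per-sample time axis in seconds.
#' @export
traceTimes <- function(trace)
  trace@t0 + (seq_len(nrow(trace@samples)) - 1) / trace@fs

#' @describeIn featureSeries frame timestamps.
#' @param x a \code{FeatureSeries}.
#' @export
featureTimes <- function(x) x@times

#' @describeIn featureSeries feature values.
#' @export
featureValues <- function(x) x@values

#' @describeIn stft bin centre frequencies of a \code{Spectrogram}.
#' @param spectrogram a \code{Spectrogram}.
#' @export
spectroFreqs <- function(spectrogram) spectrogram@freqs

#' @describeIn stft frame timestamps of a \code{Spectrogram}.
#' @export
spectroTimes <- function(spectrogram) spectrogram@times

#' @describeIn stft magnitude matrix (bins x frames) for one channel.
#' @param channel channel name or index.
#' @export
spectroMagnitudes <- function(spectrogram, channel = 1L)
  spectrogram@magnitudes[[channel]]

#' @describeIn calibrateTrigger calibrated per-channel thresholds (mV).
#' @export
triggerThresholds <- function(config) config@thresholds

## ---- show ------------------------------------------------------------------

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("SignalTrace: %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              traceDuration(object)))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d bins x %d frames, %d channel(s)\n",
              length(object@freqs), length(object@times),
              length(object@channelNames)))
  cat(sprintf("  fs %g Hz, fftLen %d, hop %d, taper %s; bin spacing %.3f Hz\n",
              object@config@fs, object@config@fftLen, object@config@hop,
              object@config@taper, object@config@fs / object@config@fftLen))
})

setMethod("show", "FeatureSeries", function(object) {
  cat(sprintf("FeatureSeries '%s' [%s] on channel '%s': %d frames\n",
              object@feature, object@units, object@channel,
              length(object@times)))
})

setMethod("show", "TriggerConfig", function(object) {
  cat(sprintf("TriggerConfig: mode %s, threshold fraction %.2f, debounce %d, release %.2f\n",
              object@mode, object@thresholdFraction, object@debounceFrames,
              object@releaseFraction))
  if (object@mode == "STFT_BAND")
    cat(sprintf("  band: %g-%g Hz\n", object@band[1], object@band[2]))
  if (length(object@thresholds))
    cat("  thresholds (mV):",
        paste(sprintf("%s=%.3g", names(object@thresholds), object@thresholds),
              collapse = ", "), "\n")
  else cat("  thresholds: <uncalibrated>\n")
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf("SubjectProfile: peak %.1f Hz, contraction %.1f mV, rest %.1f mV, bandGain %.2f, seed %d\n",
              object@spectralPeakHz, object@contractionMv, object@restNoiseMv,
              object@bandGain, object@seed))
  cat("  gains:", paste(sprintf("%s=%.3f", names(object@gains), object@gains),
                        collapse = ", "), "\n")
})
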