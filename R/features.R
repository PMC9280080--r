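## Time-domain and frequency-domain EMG features.

#' Rectified integrated EMG over a window
#'
#' Discretises the integral of the full-wave rectified signal over the window
#' with the rectangular rule at the sampling rate: \code{sum(|x|) / fs}.
#' This is the window integral of the envelope a typical sEMG sensor module
#' reports.
#'
#' @param window numeric samples (mV).
#' @param fs sampling rate in Hz.
#' @return the integral in mV s.
#' @export
riemg <- function(window, fs) {
  if (length(window) == 0L) stop("empty input: riemg needs a non-empty window")
  stopifnot(fs > 0)
  sum(abs(window)) / fs
}

#' Root mean square of a window
#'
#' \code{sqrt(mean(x^2))}: the classical time-domain amplitude feature.
#'
#' @param window numeric samples (mV).
#' @return RMS amplitude in mV.
#' @export
rmsAmplitude <- function(window) {
  if (length(window) == 0L) stop("empty input: rmsAmplitude needs a non-empty window")
  sqrt(mean(window^2))
}

#' Tapered one-sided periodogram
#'
#' Power values are scaled so that \code{sum(values) * (fs / L)} equals the
#' mean square of the tapered window (a per-window Parseval identity); bin
#' spacing is \code{fs / length(window)}.
#'
#' @param window numeric samples (length >= 2).
#' @param fs sampling rate in Hz.
#' @param taper taper shape applied before the FFT ("rectangular" default:
#'   a plain periodogram).
#' @return a \code{\link{PowerSpectrum}} of kind "psd".
#' @export
psd <- function(window, fs, taper = "rectangular") {
  L <- length(window)
  if (L < 2L) stop("psd needs a window of length >= 2")
  g <- taperWindow(taper, L)
  X <- stats::fft(g * window)
  nb <- L %/% 2L + 1L
  p <- Mod(X[seq_len(nb)])^2
  w <- rep(2, nb); w[1] <- 1
  if (L %% 2L == 0L) w[nb] <- 1
  powerSpectrum(freqs = (0:(nb - 1L)) * fs / L, values = w * p / (L * fs),
                kind = "psd")
}

## Per-bin power and uniform bin spacing of a PowerSpectrum.
spectrumPower <- function(spectrum) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  if (spectrum@kind == "psd") spectrum@values else spectrum@values^2
}

spectrumIntensity <- function(spectrum) {
  if (spectrum@kind == "magnitude") spectrum@values else sqrt(spectrum@values)
}

#' Median frequency of a spectrum
#'
#' The frequency below which half of the total spectral power lies.  Each
#' bin's power is treated as spread uniformly across its width, and the
#' crossing point is located by linear interpolation inside the crossing bin,
#' which removes bin-width quantisation: two equal bins at 60 and 80 Hz give
#' exactly 70 Hz.
#'
#' @param spectrum a \code{\link{PowerSpectrum}} (PSD or magnitude; magnitude
#'   values are squared into power).
#' @return median frequency in Hz.
#' @export
fmed <- function(spectrum) {
  p <- spectrumPower(spectrum)
  total <- sum(p)
  if (total <= 0) stop("degenerate spectrum: total power is zero")
  f <- spectrum@freqs
  if (length(f) == 1L) return(f)
  df <- diff(f)
  if (diff(range(df)) > 1e-9 * mean(df))
    stop("fmed requires uniformly spaced frequency bins")
  delta <- df[1]
  cum <- cumsum(p)
  half <- total / 2
  k <- which(cum >= half)[1]
  lower <- if (k == 1L) 0 else cum[k - 1L]
  (f[k] - delta / 2) + (half - lower) / p[k] * delta
}

#' Mean frequency of a spectrum
#'
#' The intensity-weighted mean of the bin frequencies,
#' \code{sum(I * f) / sum(I)}.  Weights are linear magnitudes by default,
#' which keeps the feature invariant to the overall signal scale; decibel
#' weighting (relative to the peak bin) is available but couples the value to
#' an arbitrary reference level.
#'
#' @param spectrum a \code{\link{PowerSpectrum}}.
#' @param dB if TRUE, weight by decibels above a -120 dB floor relative to
#'   the peak bin instead of linear magnitude.
#' @return mean frequency in Hz.
#' @export
fmean <- function(spectrum, dB = FALSE) {
  I <- spectrumIntensity(spectrum)
  if (sum(I) <= 0) stop("degenerate spectrum: total intensity is zero")
  if (dB) {
    ref <- max(I)
    I <- pmax(20 * log10(pmax(I / ref, 1e-6)) + 120, 0)
  }
  sum(spectrum@freqs * I) / sum(I)
}

#' Mean spectral magnitude inside a frequency band
#'
#' Averages the magnitudes of all bins whose centre frequency lies in the
#' closed interval \code{[loHz, hiHz]}.  The mean (rather than the sum) keeps
#' the value insensitive to the FFT length, so a threshold in mV transfers
#' across window configurations.
#'
#' @param freqs bin centre frequencies in Hz.
#' @param magnitudes per-bin linear magnitudes in mV.
#' @param loHz,hiHz band edges in Hz (default 60-80, the fixed trigger band).
#' @return mean in-band magnitude in mV.
#' @export
bandMagnitude <- function(freqs, magnitudes, loHz = 60, hiHz = 80) {
  stopifnot(length(freqs) == length(magnitudes), loHz < hiHz)
  sel <- freqs >= loHz & freqs <= hiHz
  if (!any(sel)) stop("empty band: no bin centres in [", loHz, ", ", hiHz, "] Hz")
  mean(magnitudes[sel])
}
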