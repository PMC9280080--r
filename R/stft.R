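## Batch and streaming short-time Fourier transform.

## One-sided amplitude scale: 2/sum(g) for interior bins, 1/sum(g) for DC and
## Nyquist, so an on-bin unit sinusoid reads ~1 mV in its bin and thresholds
## are in input-mV units.
stftScale <- function(g, nb, L) {
  w <- rep(2, nb); w[1] <- 1
  if (L %% 2L == 0L) w[nb] <- 1
  w / sum(g)
}

## FFT magnitudes for one channel given 0-based frame starts.
stftMagnitudes <- function(x, starts, config) {
  L <- config@fftLen
  nb <- L %/% 2L + 1L
  g <- taperWindow(config@taper, L)
  sc <- stftScale(g, nb, L)
  if (!length(starts)) return(matrix(0, nb, 0))
  frames <- vapply(starts, function(s) x[(s + 1):(s + L)] * g, numeric(L))
  X <- stats::mvfft(frames)
  Mod(X[seq_len(nb), , drop = FALSE]) * sc
}

#' Short-time Fourier transform of a trace
#'
#' Slides a tapered window of \code{fftLen} samples across each channel at a
#' stride of \code{hop} samples and stores the one-sided magnitude spectrum
#' of every frame.  Frames are stamped with the time of their last sample:
#' with the 256/64 defaults at 1100 Hz a frame is available 232.7 ms after
#' the first sample it covers, and successive frames arrive every 58.2 ms.
#'
#' @param trace a \code{\link{SignalTrace}}.
#' @param config an \code{\link{STFTConfig}}; its \code{fs} must match the
#'   trace.
#' @return a \code{\link{Spectrogram}} (empty when the trace is shorter than
#'   one frame).
#' @examples
#' tr <- signalTrace(sin(2 * pi * 68.75 * (0:1099) / 1100), fs = 1100)
#' sg <- stft(tr, stftConfig(taper = "rectangular"))
#' spectroFreqs(sg)[which.max(spectroMagnitudes(sg)[, 1])]
#' @export
stft <- function(trace, config = stftConfig()) {
  stopifnot(is(trace, "SignalTrace"), is(config, "STFTConfig"))
  if (abs(sampleRate(trace) - config@fs) > 1e-9)
    stop("config fs (", config@fs, ") does not match trace fs (",
         sampleRate(trace), ")")
  L <- config@fftLen
  starts <- frameStarts(nSamples(trace), L, config@hop)
  mags <- lapply(seq_along(channelNames(trace)), function(j)
    stftMagnitudes(traceSamples(trace)[, j], starts, config))
  names(mags) <- channelNames(trace)
  new("Spectrogram",
      freqs = (0:(L %/% 2L)) * config@fs / L,
      times = trace@t0 + (starts + L - 1) / config@fs,
      magnitudes = mags, channelNames = channelNames(trace), config = config)
}

#' Streaming STFT
#'
#' Creates a stateful streamer that accepts sample chunks of arbitrary size
#' and emits each spectral frame as soon as its last sample has arrived.  The
#' emitted frames are identical to what batch \code{\link{stft}} on the
#' concatenated samples would produce, for any chunking.
#'
#' @param config an \code{\link{STFTConfig}}.
#' @param channelNames labels of the incoming channels.
#' @param t0 time of the first sample that will be fed, seconds.
#' @return a list with functions:
#'   \describe{
#'     \item{\code{feed(chunk)}}{append a numeric vector (single channel) or
#'       matrix of new samples; returns the frames completed by this chunk as
#'       a list of \code{list(time, magnitudes)} elements (magnitudes:
#'       bins x channels matrix).}
#'     \item{\code{spectrogram()}}{all frames emitted so far as a
#'       \code{\link{Spectrogram}}.}
#'     \item{\code{framesEmitted()}}{number of frames emitted so far.}
#'   }
#' @export
stftStreamer <- function(config = stftConfig(), channelNames = c("flexor", "extensor"),
                         t0 = 0) {
  stopifnot(is(config, "STFTConfig"))
  L <- config@fftLen
  hop <- config@hop
  nb <- L %/% 2L + 1L
  nch <- length(channelNames)
  buffer <- matrix(numeric(), 0, nch)     # pending samples (tail of stream)
  consumed <- 0L                          # samples dropped from buffer head
  frames <- list()                        # emitted magnitude matrices
  times <- numeric()

  feed <- function(chunk) {
    if (is.vector(chunk)) chunk <- matrix(chunk, ncol = 1L)
    stopifnot(ncol(chunk) == nch)
    buffer <<- rbind(buffer, chunk)
    emitted <- list()
    while (nrow(buffer) >= L) {
      win <- buffer[seq_len(L), , drop = FALSE]
      g <- taperWindow(config@taper, L)
      sc <- stftScale(g, nb, L)
      mags <- vapply(seq_len(nch), function(j)
        Mod(stats::fft(win[, j] * g))[seq_len(nb)] * sc, numeric(nb))
      tS <- t0 + (consumed + L - 1) / config@fs
      frames[[length(frames) + 1L]] <<- mags
      times[length(times) + 1L] <<- tS
      emitted[[length(emitted) + 1L]] <- list(time = tS, magnitudes = mags)
      buffer <<- buffer[-seq_len(hop), , drop = FALSE]
      consumed <<- consumed + hop
    }
    invisible(emitted)
  }

  spectrogram <- function() {
    mags <- lapply(seq_len(nch), function(j) {
      if (!length(frames)) return(matrix(0, nb, 0))
      vapply(frames, function(fr) fr[, j], numeric(nb))
    })
    names(mags) <- channelNames
    new("Spectrogram", freqs = (0:(L %/% 2L)) * config@fs / L,
        times = times, magnitudes = mags, channelNames = channelNames,
        config = config)
  }

  list(feed = feed, spectrogram = spectrogram,
       framesEmitted = function() length(frames))
}

#' In-band magnitude series from a spectrogram
#'
#' Applies \code{\link{bandMagnitude}} to every frame of every channel.
#'
#' @param spectrogram a \code{\link{Spectrogram}}.
#' @param loHz,hiHz band edges in Hz.
#' @param channel a single channel (name or index) to extract, or NULL for a
#'   named list over all channels.
#' @return a \code{\link{FeatureSeries}} (or named list of them) with feature
#'   "BANDMAG"; timestamps equal the frame timestamps.
#' @export
bandSeries <- function(spectrogram, loHz = 60, hiHz = 80, channel = NULL) {
  stopifnot(is(spectrogram, "Spectrogram"))
  one <- function(ch) {
    m <- spectrogram@magnitudes[[ch]]
    vals <- if (ncol(m)) apply(m, 2, function(col)
      bandMagnitude(spectrogram@freqs, col, loHz, hiHz)) else numeric()
    featureSeries(spectrogram@times, vals, feature = "BANDMAG",
                  channel = if (is.character(ch)) ch else spectrogram@channelNames[ch])
  }
  if (!is.null(channel)) return(one(channel))
  out <- lapply(spectrogram@channelNames, one)
  names(out) <- spectrogram@channelNames
  out
}
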