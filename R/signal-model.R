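## Readers, writers and windowing for SignalTrace objects.

#' Taper window of a given shape
#'
#' Periodic (DFT-even) forms are used, as appropriate for spectral analysis.
#'
#' @param taper "hann", "hamming" or "rectangular".
#' @param n window length in samples.
#' @return numeric vector of length \code{n}.
#' @export
taperWindow <- function(taper, n) {
  k <- 0:(n - 1)
  switch(taper,
    rectangular = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    stop("unknown taper: ", taper))
}

#' Read a two-column-or-more signal file into a SignalTrace
#'
#' CSV files need a header row, a leading time column in seconds and one
#' column per channel in mV; the sampling rate is inferred as the reciprocal
#' of the median timestamp increment.  Timestamps must be uniform to within
#' a relative tolerance of 1e-6, otherwise the file is rejected.  WAV files
#' must be IEEE float; the header sampling rate is authoritative.
#'
#' @param path file to read.
#' @param format "csv" or "wav"; inferred from the extension by default.
#' @return a \code{\link{SignalTrace}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrace(signalTrace(sin(1:100), fs = 1000, channelNames = "flexor"), f)
#' readTrace(f)
#' @export
readTrace <- function(path, format = c("auto", "csv", "wav")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wav") {
    w <- wavReadFloat(path)
    return(signalTrace(w$samples, fs = w$fs))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path, " has no data rows")
  if (ncol(df) < 2L) stop("malformed input: CSV needs a time column plus >= 1 channel")
  tm <- df[[1]]
  if (nrow(df) < 2L) stop("malformed input: need >= 2 rows to infer the sampling rate")
  dt <- diff(tm)
  mdt <- stats::median(dt)
  if (mdt <= 0) stop("malformed input: timestamps must increase")
  if (any(abs(dt - mdt) > 1e-6 * max(abs(tm), 1)))
    stop("malformed input: non-uniform timestamps (beyond 1e-6 relative tolerance)")
  samples <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(samples)) stop("malformed input: non-numeric channel data")
  nm <- sub("_mV$", "", colnames(df)[-1])
  fs <- 1 / mdt
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)  # integer ADC rates
  signalTrace(samples, fs = fs, channelNames = nm, t0 = tm[1])
}

#' Write a SignalTrace to CSV or WAV
#'
#' CSV output carries a \code{time_s} column followed by one \code{<name>_mV}
#' column per channel.  WAV output stores float32 samples with the sampling
#' rate in the header; mV values are written as-is without normalisation.
#'
#' @param trace a \code{\link{SignalTrace}}.
#' @param path destination file.
#' @param format "csv" or "wav"; inferred from the extension by default.
#' @return invisibly, \code{path}.
#' @export
writeTrace <- function(trace, path, format = c("auto", "csv", "wav")) {
  stopifnot(is(trace, "SignalTrace"))
  validObject(trace)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") {
    wavWriteFloat(traceSamples(trace), sampleRate(trace), path)
  } else {
    df <- data.frame(time_s = traceTimes(trace), check.names = FALSE)
    sm <- traceSamples(trace)
    for (j in seq_along(channelNames(trace)))
      df[[paste0(channelNames(trace)[j], "_mV")]] <- sm[, j]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

## 0-based start indices of full sliding windows; floor((n - L)/h) + 1 frames.
frameStarts <- function(n, lengthSamples, hopSamples) {
  if (n < lengthSamples) return(integer())
  seq.int(0L, n - lengthSamples, by = hopSamples)
}

#' Slice a trace into causal sliding windows
#'
#' Windows advance by \code{hopSamples}; a trailing partial window is
#' discarded.  Start indices are 0-based; each frame's timestamp is the time
#' of its last sample, so a feature computed on it is available only once the
#' window has fully arrived.
#'
#' @param trace a \code{\link{SignalTrace}}.
#' @param spec a \code{\link{WindowSpec}}.
#' @return a list of frames, each \code{list(start = <0-based index>,
#'   time = <timestamp s>, samples = <L x channels matrix>)}; empty when the
#'   trace is shorter than one window.
#' @export
traceFrames <- function(trace, spec = windowSpec()) {
  stopifnot(is(trace, "SignalTrace"), is(spec, "WindowSpec"))
  starts <- frameStarts(nSamples(trace), spec@lengthSamples, spec@hopSamples)
  sm <- traceSamples(trace)
  L <- spec@lengthSamples
  lapply(starts, function(s) {
    list(start = s,
         time = trace@t0 + (s + L - 1) / trace@fs,
         samples = sm[(s + 1):(s + L), , drop = FALSE])
  })
}
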