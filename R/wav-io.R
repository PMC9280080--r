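## Minimal RIFF/WAVE codec for IEEE float32 PCM.
## Millivolt samples are stored as-is (no normalisation) so that physical
## units survive a round trip; the sample rate in the header is authoritative.

wavWriteFloat <- function(samples, fs, path) {
  stopifnot(is.matrix(samples), nrow(samples) >= 1L)
  nch <- ncol(samples)
  n <- nrow(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- 4L * n * nch
  fmtBytes <- 18L                        # WAVE_FORMAT_IEEE_FLOAT with cbSize
  riffBytes <- 4L + (8L + fmtBytes) + (8L + dataBytes)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riffBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(as.integer(fmtBytes), con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # format 3 = float
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * nch * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 4L), con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeBin(0L, con, size = 2, endian = "little")           # cbSize
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(samples))                    # frame-major
  writeBin(interleaved, con, size = 4, endian = "little")
  invisible(NULL)
}

wavReadFloat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fs <- NULL; nch <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk precedes fmt")
      if (fmt != 3L) stop("only IEEE float WAV supported (format tag 3), got ", fmt)
      nFloats <- size %/% 4L
      raw <- readBin(con, numeric(), n = nFloats, size = 4, endian = "little")
      samples <- matrix(raw, ncol = nch, byrow = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", n = size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in ", path)
  if (nrow(samples) < 1L) stop("empty WAV file: ", path)
  list(samples = samples, fs = as.numeric(fs))
}
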