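## Synthetic two-channel sEMG generator.
##
## The contraction process is a band-limited zero-mean stochastic carrier:
## white Gaussian noise shaped by a Butterworth band-pass (30-200 Hz), a
## two-pole resonance at the subject's spectral peak, and a gentle
## second-order 80 Hz tilt that reproduces the decaying high-frequency side
## of measured sEMG spectra (per-frame mean frequency ~71 Hz at the
## defaults).  A second, out-of-band carrier (30-55 and 90-200 Hz) carries
## the remainder of the contraction energy; the split between the two is the
## subject's bandGain and is what lets amplitude variability and
## in-band-magnitude variability differ across a cohort.

rampS <- 0.1                     # raised-cosine rise/fall time, seconds
warmup <- 3000L                  # filter warm-up samples, discarded

## Resonance at the spectral peak plus the high-frequency tilt.
peakShape <- function(x, fs, peakHz) {
  r <- 0.95
  x <- as.numeric(signal::filter(1, c(1, -2 * r * cos(2 * pi * peakHz / fs), r^2), x))
  lp <- signal::butter(2, min(80 / (fs / 2), 0.95), type = "low")
  as.numeric(signal::filter(lp, x))
}

## Run current-RNG white noise through the narrowband contraction shaper.
narrowCarrier <- function(n, fs, peakHz) {
  w <- stats::rnorm(n + warmup)
  bp <- signal::butter(4, c(30, 200) / (fs / 2), type = "pass")
  x <- peakShape(as.numeric(signal::filter(bp, w)), fs, peakHz)
  x <- x[-seq_len(warmup)]
  x / sqrt(mean(x^2))
}

## Out-of-band contraction energy: 30-55 and 90-200 Hz, same spectral tilt.
wideCarrier <- function(n, fs) {
  lo <- as.numeric(signal::filter(
    signal::butter(4, c(30, 55) / (fs / 2), type = "pass"),
    stats::rnorm(n + warmup)))
  hi <- as.numeric(signal::filter(
    signal::butter(4, c(90, 200) / (fs / 2), type = "pass"),
    stats::rnorm(n + warmup)))
  x <- 0.6 * lo / sqrt(mean(lo^2)) + 0.5 * hi / sqrt(mean(hi^2))
  lp <- signal::butter(2, min(80 / (fs / 2), 0.95), type = "low")
  x <- as.numeric(signal::filter(lp, x))[-seq_len(warmup)]
  x / sqrt(mean(x^2))
}

## Low-frequency motion artifact confined below cutoffHz (steep 4th-order
## low-pass: a shallower filter leaks real energy into the trigger band).
motionArtifact <- function(n, fs, cutoffHz, rmsMv) {
  if (rmsMv <= 0) return(numeric(n))
  lp <- signal::butter(4, min(cutoffHz / (fs / 2), 0.95), type = "low")
  x <- as.numeric(signal::filter(lp, stats::rnorm(n + warmup)))[-seq_len(warmup)]
  x / sqrt(mean(x^2)) * rmsMv
}

#' Validate episode labels
#'
#' Labels are a data frame with columns \code{start_s}, \code{end_s} and
#' \code{state} (FLEX, EXT or REST).  Intervals must be sorted, non-empty,
#' contiguous (no gaps or overlaps) and start at 0, so that they tile the
#' whole episode.
#'
#' @param start_s,end_s interval edges in seconds.
#' @param state one of "FLEX", "EXT", "REST" per interval.
#' @return the validated labels data frame.
#' @export
episodeLabels <- function(start_s, end_s, state) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   state = as.character(state), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("invalid labels: need at least one interval")
  if (!all(df$state %in% c("FLEX", "EXT", "REST")))
    stop("invalid labels: state must be FLEX, EXT or REST")
  if (any(df$end_s <= df$start_s)) stop("invalid labels: intervals must have end > start")
  if (abs(df$start_s[1]) > 1e-9) stop("invalid labels: first interval must start at 0")
  if (nrow(df) > 1L && any(abs(df$start_s[-1] - df$end_s[-nrow(df)]) > 1e-9))
    stop("invalid labels: intervals must be contiguous and sorted")
  df
}

#' Synthesise a labelled two-channel sEMG episode
#'
#' During FLEX intervals the flexor channel carries the contraction process
#' while the extensor stays near its resting level (plus a cross-talk
#' fraction), and vice versa for EXT.  Activation envelopes use raised-cosine
#' ramps of 100 ms, so onsets are smooth and latency measurements are
#' well-defined.  Powerline and motion artifacts are added to both channels
#' (common mode); broadband noise is independent per channel.  The episode is
#' fully reproducible from the profile's seed.
#'
#' @param profile a \code{\link{SubjectProfile}}.
#' @param labels an \code{\link{episodeLabels}} data frame.
#' @param artifacts an \code{\link{ArtifactSpec}} (default: clean).
#' @param fs sampling rate in Hz (>= 500; default 1100, the embedded ADC
#'   rate).
#' @param crossTalk fraction of the agonist contraction amplitude bleeding
#'   into the antagonist channel (default 0.1).
#' @param durationS episode duration; defaults to the end of the last label.
#'   Labels extending beyond it are an error.
#' @return a two-channel \code{\link{SignalTrace}} ("flexor", "extensor").
#' @examples
#' lb <- episodeLabels(c(0, 1, 3), c(1, 3, 4), c("REST", "FLEX", "REST"))
#' tr <- synthEpisode(subjectProfile(seed = 1), lb)
#' @export
synthEpisode <- function(profile, labels, artifacts = artifactSpec(),
                         fs = 1100, crossTalk = 0.1, durationS = NULL) {
  stopifnot(is(profile, "SubjectProfile"), is(artifacts, "ArtifactSpec"))
  validObject(profile); validObject(artifacts)
  if (fs < 500) stop("fs must be >= 500 Hz for the 0-250 Hz content modelled")
  labels <- episodeLabels(labels$start_s, labels$end_s, labels$state)
  if (is.null(durationS)) durationS <- max(labels$end_s)
  if (max(labels$end_s) > durationS + 1e-9)
    stop("invalid labels: intervals extend beyond the requested duration")
  n <- round(durationS * fs)
  if (n < 1L) stop("episode duration too short for one sample")

  chans <- c("flexor", "extensor")
  gains <- profile@gains
  if (!all(chans %in% names(gains)) && length(gains) == 2L) names(gains) <- chans

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(profile@seed)

  wb <- profile@bandGain
  ww <- sqrt(1 - wb^2)
  carriers <- lapply(chans, function(ch) {
    nc <- narrowCarrier(n, fs, profile@spectralPeakHz)
    wc <- wideCarrier(n, fs)
    x <- wb * nc + ww * wc
    x / sqrt(mean(x^2))
  })
  names(carriers) <- chans

  env <- lapply(chans, function(ch) activationEnvelope(labels, ch, n, fs,
                                                       profile, gains, crossTalk))
  names(env) <- chans

  samples <- cbind(flexor = carriers$flexor * env$flexor,
                   extensor = carriers$extensor * env$extensor)

  if (artifacts@powerlineAmpMv > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    pl <- artifacts@powerlineAmpMv *
      sin(2 * pi * artifacts@powerlineHz * (0:(n - 1)) / fs + phase)
    samples <- samples + pl
  }
  if (artifacts@motionAmpMv > 0) {
    mo <- motionArtifact(n, fs, artifacts@motionCutoffHz, artifacts@motionAmpMv)
    samples <- samples + mo
  }
  if (artifacts@broadbandNoiseMv > 0)
    samples <- samples + matrix(stats::rnorm(2L * n, sd = artifacts@broadbandNoiseMv),
                                n, 2L)

  signalTrace(samples, fs = fs, channelNames = chans)
}

## Per-sample activation level for one channel: resting level outside the
## channel's own contractions, the contraction level inside them, a cross-talk
## level while the antagonist is active, with raised-cosine transitions at
## interval boundaries.
activationEnvelope <- function(labels, channel, n, fs, profile, gains, crossTalk) {
  g <- gains[[channel]]
  restLv <- profile@restNoiseMv * g
  contrLv <- profile@contractionMv * g
  xtalkLv <- sqrt(restLv^2 + (crossTalk * contrLv)^2)
  own <- if (channel == "flexor") "FLEX" else "EXT"
  other <- if (channel == "flexor") "EXT" else "FLEX"
  lv <- vapply(labels$state, function(s)
    if (s == own) contrLv else if (s == other) xtalkLv else restLv, numeric(1))

  env <- numeric(n)
  idx <- pmin(pmax(round(labels$start_s * fs), 0L) + 1L, n)
  bounds <- c(idx, n + 1L)
  for (i in seq_len(nrow(labels)))
    env[bounds[i]:min(bounds[i + 1L] - 1L, n)] <- lv[i]
  nr <- max(2L, round(rampS * fs))
  rc <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  for (i in seq_len(nrow(labels))[-1]) {
    b <- bounds[i]
    if (b > n) next
    k <- b:min(b + nr - 1L, n)
    env[k] <- lv[i - 1L] + (lv[i] - lv[i - 1L]) * rc[seq_along(k)]
  }
  env
}

#' Rectify and integrate a trace (sensor envelope emulation)
#'
#' Full-wave rectification followed by a first-order low-pass (exponential
#' smoothing with time constant \code{tauS} and unit DC gain), per channel.
#' This reproduces the envelope output mode of integrated sEMG sensor
#' modules.
#'
#' @param trace a \code{\link{SignalTrace}}.
#' @param tauS smoothing time constant in seconds (> 0).
#' @return a \code{\link{SignalTrace}} of non-negative envelope values.
#' @export
rectifyIntegrate <- function(trace, tauS) {
  stopifnot(is(trace, "SignalTrace"), tauS > 0)
  a <- exp(-1 / (sampleRate(trace) * tauS))
  sm <- apply(traceSamples(trace), 2, function(x)
    as.numeric(stats::filter((1 - a) * abs(x), a, method = "recursive")))
  signalTrace(sm, fs = sampleRate(trace), channelNames = channelNames(trace),
              t0 = trace@t0)
}

#' Generate a cohort of subject profiles
#'
#' Per-subject amplitude gains are drawn log-normally so that the relative
#' SD of contraction RMS across the cohort approximates \code{rmsSpread},
#' while each subject's in-band amplitude fraction (bandGain) co-varies with
#' the gain so that the relative SD of the 60-80 Hz band magnitude
#' approximates \code{bandSpread}.  Defaults are the coefficients of
#' variation observed across real subjects (0.46 for RMS, 0.43 for the band
#' magnitude).  Spectral peaks vary mildly around 70 Hz.  Fully seeded.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param rmsSpread target relative SD of contraction RMS.
#' @param bandSpread target relative SD of contraction band magnitude.
#' @param seed integer seed for the cohort draw; per-subject episode seeds
#'   are derived deterministically.
#' @param profile base \code{\link{SubjectProfile}} supplying nominal levels.
#' @return a list of \code{\link{SubjectProfile}} objects.
#' @export
makeCohort <- function(nSubjects, rmsSpread = 0.46, bandSpread = 0.43,
                       seed = 0L, profile = subjectProfile()) {
  stopifnot(nSubjects >= 1L, rmsSpread >= 0, bandSpread >= 0)
  subjectSeed <- function(i)
    as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
  if (nSubjects == 1L) {
    p <- profile
    p@gains[] <- 1
    p@seed <- subjectSeed(1L)
    return(list(p))
  }
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  z <- stats::rnorm(nSubjects)
  zp <- stats::rnorm(nSubjects)
  sr <- sqrt(log(1 + rmsSpread^2))
  sb <- sqrt(log(1 + bandSpread^2))
  gains <- exp(sr * z - sr^2 / 2)
  bandGains <- pmin(pmax(profile@bandGain * exp((sb - sr) * z), 0.25), 0.95)
  peaks <- pmin(pmax(profile@spectralPeakHz + 3 * zp, 63), 77)
  lapply(seq_len(nSubjects), function(i) {
    p <- profile
    p@gains[] <- gains[i]
    p@bandGain <- bandGains[i]
    p@spectralPeakHz <- peaks[i]
    p@seed <- subjectSeed(i)
    p
  })
}

## Clone a profile with a different episode seed (internal).
reseedProfile <- function(profile, offset) {
  profile@seed <- as.integer((as.numeric(profile@seed) + 7919 * offset) %% 2147483647)
  profile
}
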