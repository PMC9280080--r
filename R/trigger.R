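## Threshold calibration and the FLEX/EXT/REST decision state machine.

#' Calibrate per-channel trigger thresholds
#'
#' Sets each channel's threshold to \code{fraction} times the maximum feature
#' value observed over the whole calibration recording (the 50 percent rule
#' by default).  The calibration series is first smoothed with the config's
#' trailing moving average (\code{smoothFrames}), exactly as the controller
#' smooths its runtime features, so calibration and operation see the same
#' statistic.  A calibration series must actually contain a contraction: a
#' series whose maximum does not exceed three times its median is rejected.
#'
#' @param calibration named list of \code{\link{FeatureSeries}} (one per
#'   channel, e.g. \code{flexor} and \code{extensor}) recorded while the
#'   subject contracts each muscle.
#' @param fraction threshold fraction of the calibration maximum.
#' @param config a template \code{\link{TriggerConfig}} supplying mode, band
#'   and state-machine parameters.
#' @return the config with \code{thresholds} filled in (and
#'   \code{thresholdFraction} set to \code{fraction}).
#' @examples
#' fs <- featureSeries(1:10, c(rep(1, 9), 10), feature = "BANDMAG", channel = "flexor")
#' calibrateTrigger(list(flexor = fs, extensor = fs),
#'                  config = triggerConfig(smoothFrames = 1))
#' @export
calibrateTrigger <- function(calibration, fraction = 0.5,
                             config = triggerConfig()) {
  stopifnot(is.list(calibration), length(calibration) >= 1L,
            !is.null(names(calibration)), is(config, "TriggerConfig"))
  thr <- vapply(names(calibration), function(ch) {
    s <- calibration[[ch]]
    stopifnot(is(s, "FeatureSeries"))
    v <- featureValues(s)
    if (!length(v)) stop("calibration failed: empty series for channel ", ch)
    v <- smoothTrailing(v, config@smoothFrames)
    if (max(v) <= 3 * stats::median(v))
      stop("calibration failed: no contraction detected on channel ", ch,
           " (max <= 3 x median)")
    fraction * max(v)
  }, numeric(1))
  config@thresholdFraction <- fraction
  config@thresholds <- thr
  validObject(config)
  config
}

#' Classify a single feature frame
#'
#' Antagonist logic with hysteresis: FLEX when only the flexor channel
#' exceeds its threshold, EXT when only the extensor does, REST when neither.
#' When both exceed, the channel with the larger value-to-threshold ratio
#' wins (an exact tie keeps the previous state).  An active state persists
#' while its channel remains above \code{releaseFraction} times its
#' threshold, which prevents chattering around the trigger level.
#'
#' @param flexorValue,extensorValue feature values in mV.
#' @param config a calibrated \code{\link{TriggerConfig}} whose thresholds
#'   are named \code{flexor} and \code{extensor}.
#' @param previousState the committed state before this frame.
#' @return "FLEX", "EXT" or "REST".
#' @export
classifyFrame <- function(flexorValue, extensorValue, config,
                          previousState = "REST") {
  thr <- config@thresholds
  if (!all(c("flexor", "extensor") %in% names(thr)))
    stop("config not calibrated for channels 'flexor' and 'extensor'")
  fAbove <- flexorValue > thr[["flexor"]]
  eAbove <- extensorValue > thr[["extensor"]]
  if (fAbove && eAbove) {
    rf <- flexorValue / thr[["flexor"]]
    re <- extensorValue / thr[["extensor"]]
    if (rf > re) return("FLEX")
    if (re > rf) return("EXT")
    return(previousState)
  }
  if (fAbove) return("FLEX")
  if (eAbove) return("EXT")
  rel <- config@releaseFraction
  if (previousState == "FLEX" && flexorValue >= rel * thr[["flexor"]])
    return("FLEX")
  if (previousState == "EXT" && extensorValue >= rel * thr[["extensor"]])
    return("EXT")
  "REST"
}

## Causal trailing moving average over k frames (identity for k = 1).
smoothTrailing <- function(v, k) {
  if (k <= 1L || length(v) < 2L) return(v)
  cs <- cumsum(v)
  n <- seq_along(v)
  lo <- pmax(n - k, 0L)
  (cs - c(0, cs)[lo + 1L]) / (n - lo)
}

## Frame-wise feature pair for the controller: band magnitude (STFT mode) or
## window RMS on the raw signal (time-domain baseline), same window grid.
## The per-frame series is smoothed with a trailing moving average of
## config@smoothFrames frames: the raw band magnitude of a narrowband
## stochastic process shows deep single-frame fades (Rayleigh-like), and a
## short causal average removes them without violating causality.
controllerFeatures <- function(trace, config, window, smooth = TRUE) {
  if (config@mode == "STFT_BAND") {
    sc <- stftConfig(fftLen = window@lengthSamples, hop = window@hopSamples,
                     fs = sampleRate(trace), taper = window@taper)
    sg <- stft(trace, sc)
    bs <- bandSeries(sg, config@band[1], config@band[2])
    out <- list(times = spectroTimes(sg),
                flexor = featureValues(bs$flexor),
                extensor = featureValues(bs$extensor))
  } else {
    frs <- traceFrames(trace, window)
    times <- vapply(frs, `[[`, numeric(1), "time")
    out <- list(times = times,
                flexor = vapply(frs, function(fr) rmsAmplitude(fr$samples[, "flexor"]),
                                numeric(1)),
                extensor = vapply(frs, function(fr) rmsAmplitude(fr$samples[, "extensor"]),
                                  numeric(1)))
  }
  if (smooth) {
    out$flexor <- smoothTrailing(out$flexor, config@smoothFrames)
    out$extensor <- smoothTrailing(out$extensor, config@smoothFrames)
  }
  out
}

#' Run the trigger controller over a two-channel trace
#'
#' Computes the mode's feature (60-80 Hz band magnitude or window RMS) on
#' every sliding window, classifies each frame with
#' \code{\link{classifyFrame}}, debounces state changes
#' (\code{debounceFrames} consecutive agreeing frames are required before a
#' change is committed), and emits one motor command per frame: CLOSE_STEP
#' during FLEX, OPEN_STEP during EXT, HOLD during REST.
#'
#' @param trace a \code{\link{SignalTrace}} with channels \code{flexor} and
#'   \code{extensor}.
#' @param config a calibrated \code{\link{TriggerConfig}}.
#' @param window a \code{\link{WindowSpec}}; defaults to the embedded
#'   256/64 Hann configuration.
#' @return a list with
#'   \describe{
#'     \item{\code{events}}{data frame of motion events (\code{state},
#'       \code{onset_s}, \code{offset_s}) tiling the classified timeline,
#'       REST segments included;}
#'     \item{\code{commands}}{data frame of per-frame motor commands
#'       (\code{t_s}, \code{action});}
#'     \item{\code{states}}{the committed per-frame state vector;}
#'     \item{\code{times}}{frame timestamps.}
#'   }
#' @export
runController <- function(trace, config, window = windowSpec()) {
  stopifnot(is(trace, "SignalTrace"), is(config, "TriggerConfig"))
  if (!all(c("flexor", "extensor") %in% channelNames(trace)))
    stop("configuration error: trace must carry 'flexor' and 'extensor' channels")
  if (!length(config@thresholds))
    stop("configuration error: config is not calibrated")
  feats <- controllerFeatures(trace, config, window)
  nF <- length(feats$times)
  states <- character(nF)
  current <- "REST"
  pendingState <- NA_character_
  pendingCount <- 0L
  for (i in seq_len(nF)) {
    cand <- classifyFrame(feats$flexor[i], feats$extensor[i], config, current)
    if (cand == current) {
      pendingState <- NA_character_
      pendingCount <- 0L
    } else {
      if (identical(cand, pendingState)) pendingCount <- pendingCount + 1L
      else { pendingState <- cand; pendingCount <- 1L }
      if (pendingCount >= config@debounceFrames) {
        current <- cand
        pendingState <- NA_character_
        pendingCount <- 0L
      }
    }
    states[i] <- current
  }
  actions <- c(FLEX = "CLOSE_STEP", EXT = "OPEN_STEP", REST = "HOLD")[states]
  commands <- data.frame(t_s = feats$times, action = unname(actions),
                         stringsAsFactors = FALSE)
  events <- statesToEvents(states, feats$times,
                           hopS = if (nF > 1) diff(feats$times[1:2]) else 0)
  list(events = events, commands = commands, states = states,
       times = feats$times)
}

## Collapse a per-frame state sequence into a tiling event list.
statesToEvents <- function(states, times, hopS) {
  if (!length(states))
    return(data.frame(state = character(), onset_s = numeric(),
                      offset_s = numeric(), stringsAsFactors = FALSE))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset <- times[starts]
  offset <- c(times[starts[-1]], times[length(times)] + hopS)
  data.frame(state = r$values, onset_s = onset, offset_s = offset,
             stringsAsFactors = FALSE)
}
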