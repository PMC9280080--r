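# Shared fixtures, all generated in code.

# 4 s episode with a single 2 s flexion in the middle.
flexEpisodeLabels <- function() {
  episodeLabels(c(0, 1, 3), c(1, 3, 4), c("REST", "FLEX", "REST"))
}

# Frames (flexor channel) fully inside the contraction interval.
contractionFrameSelector <- function(times, startS = 1, endS = 3,
                                     winS = 256 / 1100) {
  times - winS >= startS - 1e-9 & times <= endS + 1e-9
}

# Splice a hard step onset at `stepAtS` from a ramped episode's rest and
# plateau segments (the generator itself always ramps over 100 ms).
stepTrace <- function(profile, seedOffset, stepAtS = 1.8, fs = 1100) {
  long <- episodeLabels(c(0, 1, 9), c(1, 9, 10), c("REST", "FLEX", "REST"))
  tr <- synthEpisode(emgband:::reseedProfile(profile, seedOffset), long, fs = fs)
  sm <- traceSamples(tr)
  nRest <- round(stepAtS * fs)
  rest <- sm[seq_len(min(nRest, round(0.9 * fs))), , drop = FALSE]
  rest <- rest[rep(seq_len(nrow(rest)), length.out = nRest), , drop = FALSE]
  plateau <- sm[(3 * fs + 1):(8 * fs), , drop = FALSE]
  signalTrace(rbind(rest, plateau), fs = fs,
              channelNames = c("flexor", "extensor"))
}

# A calibrated trigger for a profile (clean calibration episode).
calibratedConfig <- function(profile, mode = "STFT_BAND") {
  emgband:::calibrateSubject(profile, mode)
}

# Pipeline latency on a deterministic step: an on-bin 70 Hz tone of unit
# amplitude switching on at `stepAtS`, thresholds at half its steady-state
# band magnitude (the 50% rule applied to a known maximum).
sineStepDelay <- function(stepAtS = 1.8, fs = 1100, durS = 5) {
  n <- round(durS * fs)
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 68.75 * t) * (t >= stepAtS)
  tr <- signalTrace(cbind(flexor = x, extensor = numeric(n)), fs = fs)
  steady <- 1 / 5                       # on-bin unit tone averaged over 5 bins
  cfg <- triggerConfig(thresholds = c(flexor = 0.5 * steady,
                                      extensor = 0.5 * steady))
  ev <- runController(tr, cfg)$events
  ev$onset_s[ev$state == "FLEX"][1] - stepAtS
}
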