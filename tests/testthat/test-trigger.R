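test_that("calibration takes the stated fraction of the series maximum", {
  mk <- function(vals) featureSeries(seq_along(vals), vals,
                                     feature = "BANDMAG", channel = "flexor")
  cal <- list(flexor = mk(c(rep(1, 9), 10)), extensor = mk(c(rep(1, 9), 8)))
  raw <- triggerConfig(smoothFrames = 1L)     # threshold off the raw maximum
  cfg <- calibrateTrigger(cal, fraction = 0.5, config = raw)
  expect_equal(unname(triggerThresholds(cfg)), c(5, 4))
  # calibration smooths like the runtime: a lone spike is averaged down
  cfgSm <- calibrateTrigger(cal, fraction = 0.5,
                            config = triggerConfig(smoothFrames = 3L))
  expect_equal(unname(triggerThresholds(cfgSm))[1], 0.5 * mean(c(1, 1, 10)))
  # boundary: fraction 1.0 leaves only the maximum able to trigger
  cfg1 <- calibrateTrigger(cal, fraction = 0.99999, config = raw)
  expect_equal(unname(triggerThresholds(cfg1))[1], 10, tolerance = 1e-4)
  expect_false(classifyFrame(9.9, 0, cfg1) == "FLEX")
  # flat series: no contraction, calibration refused
  flat <- list(flexor = mk(rep(2, 10)), extensor = mk(rep(2, 10)))
  expect_error(calibrateTrigger(flat), "calibration failed")
})

test_that("frame classification follows the antagonist threshold logic", {
  cfg <- triggerConfig(thresholds = c(flexor = 5, extensor = 5))
  expect_equal(classifyFrame(6, 1, cfg, "REST"), "FLEX")
  expect_equal(classifyFrame(1, 6, cfg, "REST"), "EXT")
  expect_equal(classifyFrame(0, 0, cfg, "REST"), "REST")
  # both above: larger value/threshold ratio wins
  expect_equal(classifyFrame(7, 6, cfg, "REST"), "FLEX")
  cfg2 <- triggerConfig(thresholds = c(flexor = 5, extensor = 10))
  expect_equal(classifyFrame(7, 12, cfg2, "REST"), "FLEX")   # 1.4 vs 1.2
  # exact ratio tie keeps the previous state
  expect_equal(classifyFrame(6, 12, cfg2, "EXT"), "EXT")
  expect_equal(classifyFrame(6, 12, cfg2, "REST"), "REST")
})

test_that("hysteresis holds an active state down to the release level", {
  cfg <- triggerConfig(thresholds = c(flexor = 10, extensor = 10),
                       releaseFraction = 0.6)
  expect_equal(classifyFrame(8, 0, cfg, "FLEX"), "FLEX")   # above 6
  expect_equal(classifyFrame(5, 0, cfg, "FLEX"), "REST")   # below 6
  expect_equal(classifyFrame(8, 0, cfg, "REST"), "REST")   # needs > 10 to enter
  expect_equal(classifyFrame(0, 8, cfg, "EXT"), "EXT")
})

test_that("controller on a zero-signal trace stays at REST and HOLD", {
  tr <- signalTrace(matrix(0, 2200, 2), fs = 1100,
                    channelNames = c("flexor", "extensor"))
  cfg <- triggerConfig(thresholds = c(flexor = 5, extensor = 5))
  res <- runController(tr, cfg)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$state, "REST")
  expect_true(all(res$commands$action == "HOLD"))
})

test_that("thresholds above the episode maximum suppress all events", {
  tr <- synthEpisode(subjectProfile(seed = 6), flexEpisodeLabels())
  cfg <- triggerConfig(thresholds = c(flexor = 1e6, extensor = 1e6))
  res <- runController(tr, cfg)
  expect_true(all(res$events$state == "REST"))
})

test_that("a single flexion yields one FLEX event with bounded onset delay", {
  p <- subjectProfile(seed = 0)
  cfg <- calibratedConfig(p, "STFT_BAND")
  tr <- synthEpisode(emgband:::reseedProfile(p, 7L), flexEpisodeLabels())
  res <- runController(tr, cfg)
  flex <- res$events[res$events$state == "FLEX", ]
  expect_equal(nrow(flex), 1L)
  expect_false(any(res$events$state == "EXT"))
  # ramped onset: window fill (233 ms) + feature smoothing (2 hops) + ramp
  expect_lte(flex$onset_s[1] - 1, 0.48)
  expect_gte(flex$onset_s[1] - 1, 0)
})

test_that("controller output is deterministic and commands map to states", {
  p <- subjectProfile(seed = 1)
  cfg <- calibratedConfig(p, "STFT_BAND")
  tr <- synthEpisode(emgband:::reseedProfile(p, 8L), flexEpisodeLabels())
  r1 <- runController(tr, cfg)
  r2 <- runController(tr, cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$commands, r2$commands)
  map <- c(FLEX = "CLOSE_STEP", EXT = "OPEN_STEP", REST = "HOLD")
  expect_equal(r1$commands$action, unname(map[r1$states]))
  expect_equal(nrow(r1$commands), length(r1$times))
})

test_that("raising a threshold never increases that channel's triggered time", {
  p <- subjectProfile(seed = 2)
  base <- calibratedConfig(p, "STFT_BAND")
  tr <- synthEpisode(emgband:::reseedProfile(p, 9L),
                     makeTrialLabels(3L, 3L))
  flexTime <- function(cfg) {
    ev <- runController(tr, cfg)$events
    sum(ev$offset_s[ev$state == "FLEX"] - ev$onset_s[ev$state == "FLEX"])
  }
  durations <- vapply(c(0.8, 1, 1.3, 1.8, 3), function(mult) {
    cfg <- base
    cfg@thresholds["flexor"] <- cfg@thresholds["flexor"] * mult
    flexTime(cfg)
  }, numeric(1))
  expect_true(all(diff(durations) <= 1e-9))
})

test_that("debounce delays commitment by the required number of frames", {
  # feature series crafted directly through a synthetic two-frame blip
  cfg <- triggerConfig(thresholds = c(flexor = 5, extensor = 5),
                       debounceFrames = 3L, smoothFrames = 1L)
  # with debounce 3, a 2-frame excursion must not commit
  states <- character()
  cur <- "REST"; pend <- NA_character_; cnt <- 0L
  vals <- c(1, 9, 9, 1, 1, 9, 9, 9, 1)
  for (v in vals) {
    cand <- classifyFrame(v, 0, cfg, cur)
    if (cand == cur) { pend <- NA_character_; cnt <- 0L }
    else {
      if (identical(cand, pend)) cnt <- cnt + 1L else { pend <- cand; cnt <- 1L }
      if (cnt >= cfg@debounceFrames) { cur <- cand; pend <- NA_character_; cnt <- 0L }
    }
    states <- c(states, cur)
  }
  expect_equal(states[4], "REST")       # two agreeing frames: not yet
  expect_equal(states[8], "FLEX")       # three agreeing frames: committed
})

test_that("step onsets are detected within the algorithmic latency budget", {
  # deterministic step: an on-bin 70 Hz tone switching on at t = 1.8 s
  # isolates the pipeline latency (window fill + hop + smoothing) from
  # stochastic carrier fades
  fs <- 1100
  delay <- sineStepDelay(stepAtS = 1.8, fs = fs)
  expect_lte(delay, (256 + 2 * 64) / fs)       # 349 ms of signal time
  expect_gte(delay, 0)                         # strictly causal
  # stochastic sEMG steps: the same bound plus amplitude-fade allowance
  p <- subjectProfile(seed = 5)
  cfg <- calibratedConfig(p, "STFT_BAND")
  for (s in 1:5) {
    tr <- stepTrace(p, 600L + s, stepAtS = 1.8)
    res <- runController(tr, cfg)
    flex <- res$events[res$events$state == "FLEX", ]
    expect_gte(nrow(flex), 1L)
    d <- flex$onset_s[1] - 1.8
    expect_lte(d, 0.5)
    expect_gte(d, 0)
  }
})

test_that("threshold transfer across subjects stays within 10 points (band mode)", {
  te <- transferExperiment(12L, trialsPerClass = 4L, seed = 1)
  stftRow <- te[te$mode == "STFT_BAND", ]
  expect_lt(stftRow$loss_pct, 10)
  # deterministic under the same seed
  te2 <- transferExperiment(12L, trialsPerClass = 4L, seed = 1)
  expect_identical(te, te2)
})
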