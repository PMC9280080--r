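test_that("episodes are bit-identical under the same seed", {
  lb <- flexEpisodeLabels()
  a <- synthEpisode(subjectProfile(seed = 10), lb)
  b <- synthEpisode(subjectProfile(seed = 10), lb)
  expect_identical(traceSamples(a), traceSamples(b))
  c <- synthEpisode(subjectProfile(seed = 11), lb)
  expect_false(identical(traceSamples(a), traceSamples(c)))
})

test_that("silent profile produces an all-zero trace", {
  p <- subjectProfile(restNoiseMv = 0, contractionMv = 1, seed = 0)
  tr <- synthEpisode(p, episodeLabels(0, 2, "REST"))
  expect_true(all(traceSamples(tr) == 0))
})

test_that("labels are validated", {
  expect_error(episodeLabels(c(0, 1), c(1, 0.5), c("REST", "FLEX")), "end > start")
  expect_error(episodeLabels(c(0, 2), c(1, 3), c("REST", "FLEX")), "contiguous")
  expect_error(episodeLabels(0, 1, "WIGGLE"), "state")
  expect_error(synthEpisode(subjectProfile(), episodeLabels(0, 5, "REST"),
                            durationS = 3), "beyond")
})

test_that("agonist/antagonist structure and label fidelity hold", {
  lb <- episodeLabels(c(0, 1, 3, 4, 6), c(1, 3, 4, 6, 7),
                      c("REST", "FLEX", "REST", "EXT", "REST"))
  tr <- synthEpisode(subjectProfile(seed = 2), lb)
  sm <- traceSamples(tr)
  fs <- sampleRate(tr)
  seg <- function(ch, a, b) rmsAmplitude(sm[(a * fs + 220):(b * fs - 110), ch])
  # contraction RMS > 3x rest RMS on the active channel
  expect_gt(seg("flexor", 1, 3), 3 * seg("flexor", 0, 1))
  expect_gt(seg("extensor", 4, 6), 3 * seg("extensor", 0, 1))
  # the antagonist stays near rest during the agonist's contraction
  expect_lt(seg("extensor", 1, 3), 0.25 * seg("flexor", 1, 3))
  expect_lt(seg("flexor", 4, 6), 0.25 * seg("extensor", 4, 6))
})

test_that("rectifyIntegrate implements a unit-DC-gain first-order envelope", {
  fs <- 1000
  const <- signalTrace(rep(3, 3000), fs = fs, channelNames = "flexor")
  y <- traceSamples(rectifyIntegrate(const, 0.05))[, 1]
  expect_equal(tail(y, 1), 3, tolerance = 1e-3)
  neg <- signalTrace(rep(-3, 3000), fs = fs, channelNames = "flexor")
  expect_equal(traceSamples(rectifyIntegrate(neg, 0.05)),
               traceSamples(rectifyIntegrate(const, 0.05)))
  # impulse response decays with ratio exp(-1/(fs * tau))
  imp <- numeric(100); imp[10] <- 1
  yi <- traceSamples(rectifyIntegrate(signalTrace(imp, fs = fs,
                                                  channelNames = "flexor"),
                                      0.02))[, 1]
  ratios <- yi[12:30] / yi[11:29]
  expect_equal(ratios, rep(exp(-1 / (fs * 0.02)), length(ratios)),
               tolerance = 1e-9)
  expect_true(all(yi >= 0))
})

test_that("mean contraction periodogram is concentrated in-band with a 60-80 Hz mode", {
  lb <- flexEpisodeLabels()
  meanPw <- NULL
  for (s in 1:20) {
    tr <- synthEpisode(subjectProfile(seed = s), lb)
    sg <- stft(tr)
    sel <- contractionFrameSelector(spectroTimes(sg))
    pw <- rowMeans(spectroMagnitudes(sg, "flexor")[, sel]^2)
    meanPw <- if (is.null(meanPw)) pw else meanPw + pw
  }
  f <- spectroFreqs(sg)
  modal <- f[which.max(meanPw)]
  expect_gte(modal, 60)
  expect_lte(modal, 80)
  expect_gte(sum(meanPw[f >= 30 & f <= 200]) / sum(meanPw[-1]), 0.95)
})

test_that("per-frame mean frequency of contractions sits in the 60-82 Hz range", {
  lb <- flexEpisodeLabels()
  for (s in c(1, 5, 9)) {
    tr <- synthEpisode(subjectProfile(seed = s), lb)
    sg <- stft(tr)
    sel <- contractionFrameSelector(spectroTimes(sg))
    M <- spectroMagnitudes(sg, "flexor")[, sel]
    f <- spectroFreqs(sg)
    fm <- mean(apply(M, 2, function(m) sum(f * m) / sum(m)))
    expect_gte(fm, 60)
    expect_lte(fm, 82)
  }
})

test_that("artifacts at rest barely move the band magnitude but inflate RMS", {
  rest <- episodeLabels(0, 25, "REST")
  art <- artifactSpec(powerlineAmpMv = 0.3 * 400, motionAmpMv = 0.5 * 400)
  bandChange <- rmsRise <- numeric(5)
  for (s in 1:5) {
    p <- subjectProfile(seed = 40 + s)
    clean <- synthEpisode(p, rest)
    dirty <- synthEpisode(p, rest, artifacts = art)
    b0 <- mean(featureValues(bandSeries(stft(clean), channel = "flexor")))
    b1 <- mean(featureValues(bandSeries(stft(dirty), channel = "flexor")))
    bandChange[s] <- abs(b1 / b0 - 1)
    rmsRise[s] <- rmsAmplitude(traceSamples(dirty)[, 1]) /
      rmsAmplitude(traceSamples(clean)[, 1]) - 1
  }
  expect_lt(max(bandChange), 0.05)
  expect_gt(min(rmsRise), 0.5)
})

test_that("cohort generation is seeded and recovers the RMS spread", {
  one <- makeCohort(1, seed = 3)
  expect_length(one, 1L)
  expect_true(all(one[[1]]@gains == 1))
  expect_identical(lapply(makeCohort(8, seed = 5), function(p) p@gains),
                   lapply(makeCohort(8, seed = 5), function(p) p@gains))
  # Monte-Carlo: relative SD of simulated contraction RMS near the target
  cohort <- makeCohort(100, rmsSpread = 0.4, seed = 17)
  lb <- episodeLabels(c(0, 0.5), c(0.5, 2.5), c("REST", "FLEX"))
  contrRms <- vapply(cohort, function(p) {
    sm <- traceSamples(synthEpisode(p, lb))
    rmsAmplitude(sm[(0.7 * 1100):(2.4 * 1100), "flexor"])
  }, numeric(1))
  cv <- sd(contrRms) / mean(contrRms)
  expect_lt(abs(cv - 0.4), 0.1)
})
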