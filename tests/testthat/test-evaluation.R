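test_that("the packaged fixture is structurally valid", {
  fx <- table3Fixture()
  expect_equal(nrow(fx), 10L)
  for (f in c("rms", "fmean", "fmed", "band")) {
    expect_true(all(fx[[paste0(f, "_min")]] <= fx[[paste0(f, "_mean")]]))
    expect_true(all(fx[[paste0(f, "_mean")]] <= fx[[paste0(f, "_max")]]))
  }
})

test_that("fixture summaries reduce to mean and chosen-divisor SD", {
  fx <- table3Fixture()
  s <- table3Summary(fx, "FMEAN", "population")
  expect_equal(unname(s["mean"]), mean(fx$fmean_mean))
  expect_equal(unname(s["sd"]),
               sqrt(mean((fx$fmean_mean - mean(fx$fmean_mean))^2)))
  s2 <- table3Summary(fx, "BANDMAG", "sample")
  expect_equal(unname(s2["sd"]), sd(fx$band_mean))
  # a constant fixture gives (c, 0)
  fxc <- fx
  for (cl in grep("band", names(fxc), value = TRUE)) fxc[[cl]] <- 7
  expect_equal(unname(table3Summary(fxc, "BANDMAG", "sample")), c(7, 0))
})

test_that("trial scoring follows the overlap rules", {
  lb <- makeTrialLabels(1L, 1L)   # REST FLEX REST EXT REST
  perfect <- data.frame(state = lb$state, onset_s = lb$start_s,
                        offset_s = lb$end_s, stringsAsFactors = FALSE)
  expect_true(all(scoreEpisode(perfect, lb)$correct))
  # no events at all: rest labels correct, motion labels not
  none <- perfect[0, ]
  sc <- scoreEpisode(none, lb)
  expect_true(all(sc$correct[sc$state == "REST"]))
  expect_false(any(sc$correct[sc$state != "REST"]))
  restOnly <- episodeLabels(c(0, 3), c(3, 6), c("REST", "REST"))
  expect_true(all(scoreEpisode(none, restOnly)$correct))
  # a wrong-state event overlapping a motion trial sinks it
  lb2 <- episodeLabels(c(0, 1, 3), c(1, 3, 4), c("REST", "FLEX", "REST"))
  wrong <- data.frame(state = "EXT", onset_s = 1.2, offset_s = 2.8)
  expect_false(scoreEpisode(wrong, lb2)$correct[2])
  # an event covering less than half the trial does not count
  small <- data.frame(state = "FLEX", onset_s = 1.0, offset_s = 1.8)
  expect_false(scoreEpisode(small, lb2)$correct[2])
  # detection latency spilling into the next rest is tolerated up to a
  # quarter of the rest's duration
  lagged <- data.frame(state = "FLEX", onset_s = 1.3, offset_s = 3.2)
  sc3 <- scoreEpisode(lagged, lb2)
  expect_true(sc3$correct[2])
  expect_true(sc3$correct[3])
  deepSpill <- data.frame(state = "FLEX", onset_s = 1.3, offset_s = 3.6)
  expect_false(scoreEpisode(deepSpill, lb2)$correct[3])
})

test_that("trial labels tile the protocol timeline", {
  lb <- makeTrialLabels(20L, 20L)
  expect_equal(sum(lb$state == "FLEX"), 20L)
  expect_equal(sum(lb$state == "EXT"), 20L)
  expect_equal(max(lb$end_s), 2 + 40 * 4)    # 4 s cadence per movement
  expect_true(all(lb$start_s[-1] == lb$end_s[-nrow(lb)]))
})

test_that("a small clean cohort reaches high accuracy in band mode", {
  rep <- cohortExperiment(4L, trialsPerClass = 4L, mode = "STFT_BAND",
                          seed = 11)
  expect_gte(rep$overall_pct, 90)
  expect_equal(rep$per_class$n_trials[rep$per_class$state == "FLEX"], 16L)
  # weighted overall equals trial-weighted mean of per-class accuracies
  pc <- rep$per_class
  expect_equal(rep$overall_pct,
               sum(pc$accuracy_pct * pc$n_trials) / sum(pc$n_trials))
  # reproducible
  rep2 <- cohortExperiment(4L, trialsPerClass = 4L, mode = "STFT_BAND",
                           seed = 11)
  expect_identical(rep, rep2)
})

test_that("unreachable thresholds zero the motion classes but keep REST", {
  # replicate the cohort run but overriding the calibrated thresholds
  cohort <- makeCohort(2L, seed = 3)
  labels <- makeTrialLabels(3L, 3L)
  cfg <- triggerConfig(thresholds = c(flexor = 1e7, extensor = 1e7))
  ok <- c(FLEX = 0L, EXT = 0L, REST = 0L)
  n <- c(FLEX = 0L, EXT = 0L, REST = 0L)
  for (p in cohort) {
    tr <- synthEpisode(p, labels)
    sc <- scoreEpisode(runController(tr, cfg)$events, labels)
    for (st in names(ok)) {
      ok[st] <- ok[st] + sum(sc$correct[sc$state == st])
      n[st] <- n[st] + sum(sc$state == st)
    }
  }
  expect_equal(unname(ok[c("FLEX", "EXT")]), c(0L, 0L))
  expect_equal(ok[["REST"]], n[["REST"]])
})

test_that("variability report recovers degenerate cases exactly", {
  # identical subjects: zero CV
  same <- replicate(4, list(RMS = c(10, 10), BANDMAG = c(2, 2)),
                    simplify = FALSE)
  vr <- variabilityReport(same)
  expect_true(all(vr$cv == 0))
  expect_true(all(vr$span == 0))
  # two subjects with contraction means 10 and 20: span 10
  two <- list(list(RMS = 10), list(RMS = 20))
  vr2 <- variabilityReport(two)
  expect_equal(vr2$span, 10)
  expect_equal(vr2$mean, 15)
  # FeatureSeries inputs are averaged the same way
  fsIn <- list(list(RMS = featureSeries(1:3, c(9, 10, 11), feature = "RMS")),
               list(RMS = featureSeries(1:3, c(19, 20, 21), feature = "RMS")))
  expect_equal(variabilityReport(fsIn)$span, 10)
})

test_that("contraction feature collection pools the active channel", {
  lb <- makeTrialLabels(2L, 2L)
  tr <- synthEpisode(subjectProfile(seed = 14), lb)
  cf <- contractionFeatures(tr, lb)
  expect_s4_class(cf$RMS, "FeatureSeries")
  expect_s4_class(cf$BANDMAG, "FeatureSeries")
  expect_gt(length(featureValues(cf$RMS)), 0)
  # pooled contraction RMS is far above the resting level
  expect_gt(mean(featureValues(cf$RMS)), 200)
  expect_gt(mean(featureValues(cf$BANDMAG)), 50)
})
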