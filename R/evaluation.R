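## Evaluation: packaged feature statistics, trial scoring and synthetic
## cohort experiments.

#' Load the packaged per-test feature statistics fixture
#'
#' Ten rows (five subjects, two recording sessions each) of mean/max/min
#' statistics for four EMG features measured during repeated wrist motions:
#' window RMS (mV), mean frequency (Hz), median frequency (Hz) and the mean
#' 60-80 Hz band magnitude (mV).
#'
#' @param path CSV to read; defaults to the copy shipped with the package.
#' @return a validated data frame with one row per (subject, test).
#' @export
table3Fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table3_features.csv", package = "emgband",
                        mustWork = TRUE)
  df <- utils::read.csv(path)
  need <- c("subject", "test",
            as.vector(outer(c("rms", "fmean", "fmed", "band"),
                            c("mean", "max", "min"), paste, sep = "_")))
  if (!all(need %in% names(df)))
    stop("fixture error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) != 10L)
    stop("fixture error: expected 10 rows (5 subjects x 2 tests), got ", nrow(df))
  for (f in c("rms", "fmean", "fmed", "band")) {
    ok <- df[[paste0(f, "_min")]] <= df[[paste0(f, "_mean")]] &
      df[[paste0(f, "_mean")]] <= df[[paste0(f, "_max")]]
    if (!all(ok)) stop("fixture error: min <= mean <= max violated for ", f)
  }
  df
}

#' Mean and SD of a feature across the fixture's per-test means
#'
#' Summarises the ten per-test mean values of one feature.  \code{sdKind}
#' selects the divisor: \code{"sample"} (n - 1) or \code{"population"} (n);
#' published summaries of this kind mix both conventions, so the choice is
#' explicit.
#'
#' @param fixture the data frame from \code{\link{table3Fixture}}.
#' @param feature one of "RMS", "FMEAN", "FMED", "BANDMAG".
#' @param sdKind "sample" or "population".
#' @return named numeric \code{c(mean =, sd =)}.
#' @examples
#' table3Summary(table3Fixture(), "FMEAN", "population")
#' @export
table3Summary <- function(fixture, feature = c("RMS", "FMEAN", "FMED", "BANDMAG"),
                          sdKind = c("sample", "population")) {
  feature <- match.arg(feature)
  sdKind <- match.arg(sdKind)
  col <- c(RMS = "rms_mean", FMEAN = "fmean_mean", FMED = "fmed_mean",
           BANDMAG = "band_mean")[[feature]]
  if (!col %in% names(fixture)) stop("fixture error: missing column ", col)
  v <- fixture[[col]]
  if (any(is.na(v))) stop("fixture error: missing values in ", col)
  n <- length(v)
  s <- stats::sd(v)
  if (sdKind == "population") s <- s * sqrt((n - 1) / n)
  c(mean = mean(v), sd = s)
}

## Overlap in seconds between [a1, a2] and [b1, b2].
intervalOverlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Score controller events against episode labels
#'
#' Each labelled interval is one trial.  A FLEX or EXT trial is correct when
#' exactly one event of the matching state covers at least half of the trial
#' and no event of the opposing active state covers more than a quarter of
#' it (the quarter-slack absorbs the controller's unavoidable detection and
#' release latency spilling across trial boundaries while still flagging
#' genuine misclassifications).  A REST trial is correct when no active
#' (FLEX/EXT) event covers more than a quarter of it; an empty event list
#' therefore scores all-REST labels as fully correct.
#'
#' @param events event data frame (\code{state}, \code{onset_s},
#'   \code{offset_s}) from \code{\link{runController}}.
#' @param labels an \code{\link{episodeLabels}} data frame.
#' @return the labels data frame with a logical \code{correct} column.
#' @export
scoreEpisode <- function(events, labels) {
  labels <- episodeLabels(labels$start_s, labels$end_s, labels$state)
  active <- events[events$state != "REST", , drop = FALSE]
  labels$correct <- vapply(seq_len(nrow(labels)), function(i) {
    a1 <- labels$start_s[i]; a2 <- labels$end_s[i]
    dur <- a2 - a1
    ov <- if (nrow(active)) intervalOverlap(a1, a2, active$onset_s, active$offset_s)
          else numeric()
    if (labels$state[i] == "REST")
      return(!any(ov > 0.25 * dur))
    match_ <- active$state == labels$state[i]
    sum(ov[match_] >= 0.5 * dur) == 1L && !any(ov[!match_] > 0.25 * dur)
  }, logical(1))
  labels
}

#' Build a standard trial protocol as episode labels
#'
#' A leading rest, then \code{nFlex} flexion trials and \code{nExt} extension
#' trials, each \code{motionS} seconds of contraction preceded by
#' \code{restS} seconds of rest, and a trailing rest: the cadence of a
#' metronome-paced wrist-motion protocol (4 s per movement cycle at the
#' defaults).
#'
#' @param nFlex,nExt number of flexion / extension trials.
#' @param motionS contraction duration per trial, seconds.
#' @param restS rest duration between trials, seconds.
#' @return an \code{\link{episodeLabels}} data frame.
#' @export
makeTrialLabels <- function(nFlex = 20L, nExt = 20L, motionS = 2, restS = 2) {
  states <- c(rbind(rep("REST", nFlex + nExt),
                    c(rep("FLEX", nFlex), rep("EXT", nExt))), "REST")
  durs <- c(rbind(rep(restS, nFlex + nExt),
                  rep(motionS, nFlex + nExt)), restS)
  ends <- cumsum(durs)
  episodeLabels(c(0, ends[-length(ends)]), ends, states)
}

## Calibration protocol: a couple of contractions per muscle on clean signal.
calibrationLabels <- function(motionS = 2, restS = 2) {
  makeTrialLabels(nFlex = 2L, nExt = 2L, motionS = motionS, restS = restS)
}

## Calibrate a trigger for one subject from a clean calibration episode.
calibrateSubject <- function(profile, mode, window = windowSpec(),
                             fraction = 0.5, fs = 1100,
                             template = NULL, seedOffset = 1L) {
  if (is.null(template)) template <- triggerConfig(mode = mode)
  trace <- synthEpisode(reseedProfile(profile, seedOffset),
                        calibrationLabels(), fs = fs)
  cfg0 <- template
  cfg0@mode <- mode
  feats <- controllerFeatures(trace, cfg0, window, smooth = FALSE)
  calib <- list(
    flexor = featureSeries(feats$times, feats$flexor, feature = "BANDMAG",
                           channel = "flexor"),
    extensor = featureSeries(feats$times, feats$extensor, feature = "BANDMAG",
                             channel = "extensor"))
  calibrateTrigger(calib, fraction = fraction, config = cfg0)
}

#' Closed-loop accuracy on a synthetic cohort
#'
#' For each simulated subject: calibrate per-channel thresholds on a clean
#' calibration episode (50 percent of the feature maximum), run the
#' controller on a fresh labelled episode of \code{trialsPerClass} flexion
#' and extension trials with interleaved rests, and score every trial.
#' Per-class accuracies are averaged over subjects weighting each trial
#' equally.
#'
#' @param nSubjects cohort size.
#' @param trialsPerClass flexion/extension repetitions per subject.
#' @param mode "STFT_BAND" or "RMS".
#' @param seed cohort seed; the experiment is fully reproducible.
#' @param artifacts an \code{\link{ArtifactSpec}} applied to the test
#'   episodes (calibration is always clean).
#' @param rmsSpread,bandSpread cohort variability (see
#'   \code{\link{makeCohort}}).
#' @param window analysis window.
#' @param fs sampling rate in Hz.
#' @return a list: \code{per_class} data frame (\code{state},
#'   \code{accuracy_pct}, \code{n_trials}), \code{overall_pct} (trial-count
#'   weighted), \code{n_subjects}, \code{seed}.
#' @export
cohortExperiment <- function(nSubjects, trialsPerClass = 20L,
                             mode = c("STFT_BAND", "RMS"), seed = 0L,
                             artifacts = artifactSpec(),
                             rmsSpread = 0.46, bandSpread = 0.43,
                             window = windowSpec(), fs = 1100) {
  mode <- match.arg(mode)
  cohort <- makeCohort(nSubjects, rmsSpread, bandSpread, seed = seed)
  labels <- makeTrialLabels(trialsPerClass, trialsPerClass)
  tally <- list(FLEX = c(0L, 0L), EXT = c(0L, 0L), REST = c(0L, 0L))
  for (i in seq_along(cohort)) {
    cfg <- calibrateSubject(cohort[[i]], mode, window, fs = fs)
    trace <- synthEpisode(reseedProfile(cohort[[i]], 1000L + i), labels,
                          artifacts = artifacts, fs = fs)
    res <- runController(trace, cfg, window)
    scored <- scoreEpisode(res$events, labels)
    for (st in names(tally)) {
      sel <- scored$state == st
      tally[[st]] <- tally[[st]] + c(sum(scored$correct[sel]), sum(sel))
    }
  }
  perClass <- data.frame(
    state = names(tally),
    accuracy_pct = vapply(tally, function(x) 100 * x[1] / max(x[2], 1L),
                          numeric(1)),
    n_trials = vapply(tally, `[`, integer(1), 2L),
    stringsAsFactors = FALSE, row.names = NULL)
  nOk <- sum(vapply(tally, `[`, integer(1), 1L))
  nAll <- sum(perClass$n_trials)
  list(per_class = perClass, overall_pct = 100 * nOk / nAll,
       n_subjects = nSubjects, seed = seed)
}

#' Across-subject variability of contraction-level features
#'
#' For each feature, computes the across-subject mean, SD, coefficient of
#' variation and max-min span of the per-subject contraction-level means.
#'
#' @param cohortFeatures a list with one element per subject; each element is
#'   a named list of \code{\link{FeatureSeries}} (or bare numeric vectors)
#'   holding that subject's contraction-level feature values.
#' @return data frame with columns \code{feature}, \code{mean}, \code{sd},
#'   \code{cv}, \code{span}.
#' @export
variabilityReport <- function(cohortFeatures) {
  stopifnot(length(cohortFeatures) >= 2L)
  featNames <- names(cohortFeatures[[1]])
  stopifnot(!is.null(featNames))
  perSubject <- vapply(cohortFeatures, function(subj)
    vapply(featNames, function(f) {
      v <- subj[[f]]
      if (is(v, "FeatureSeries")) v <- featureValues(v)
      mean(v)
    }, numeric(1)), numeric(length(featNames)))
  perSubject <- matrix(perSubject, nrow = length(featNames),
                       dimnames = list(featNames, NULL))
  data.frame(
    feature = featNames,
    mean = apply(perSubject, 1, mean),
    sd = apply(perSubject, 1, sd),
    cv = apply(perSubject, 1, function(x) if (mean(x) == 0) 0 else sd(x) / mean(x)),
    span = apply(perSubject, 1, function(x) diff(range(x))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject contraction-level feature means
#'
#' Runs the analysis window over an episode and collects, for each feature,
#' the frame values whose windows lie entirely inside contraction intervals
#' of the subject's active channel (flexor frames during FLEX, extensor
#' frames during EXT).
#'
#' @param trace a two-channel episode.
#' @param labels its \code{\link{episodeLabels}}.
#' @param window analysis window.
#' @return named list of \code{\link{FeatureSeries}}: \code{RMS} and
#'   \code{BANDMAG} contraction-level values.
#' @export
contractionFeatures <- function(trace, labels, window = windowSpec()) {
  fs <- sampleRate(trace)
  sc <- stftConfig(fftLen = window@lengthSamples, hop = window@hopSamples,
                   fs = fs, taper = window@taper)
  sg <- stft(trace, sc)
  times <- spectroTimes(sg)
  winS <- window@lengthSamples / fs
  inState <- function(st) {
    iv <- labels[labels$state == st, , drop = FALSE]
    sel <- rep(FALSE, length(times))
    for (k in seq_len(nrow(iv)))
      sel <- sel | (times - winS >= iv$start_s[k] - 1e-9 &
                    times <= iv$end_s[k] + 1e-9)
    sel
  }
  frs <- traceFrames(trace, window)
  chanRms <- function(ch) vapply(frs, function(fr)
    rmsAmplitude(fr$samples[, ch]), numeric(1))
  bm <- bandSeries(sg)
  selF <- inState("FLEX"); selE <- inState("EXT")
  list(
    RMS = featureSeries(times[selF | selE],
                        c(chanRms("flexor")[selF], chanRms("extensor")[selE])[
                          order(c(times[selF], times[selE]))],
                        feature = "RMS", channel = "active"),
    BANDMAG = featureSeries(times[selF | selE],
                            c(featureValues(bm$flexor)[selF],
                              featureValues(bm$extensor)[selE])[
                              order(c(times[selF], times[selE]))],
                            feature = "BANDMAG", channel = "active"))
}

#' Threshold transfer between subjects
#'
#' Calibrates thresholds on the first subject of a cohort and applies them
#' unchanged to every other subject, comparing the resulting accuracy with
#' each subject's self-calibrated accuracy, in both controller modes.
#'
#' @param nSubjects cohort size (>= 2).
#' @param trialsPerClass trials per class per subject.
#' @param seed cohort seed.
#' @param rmsSpread,bandSpread cohort variability.
#' @param window analysis window.
#' @param fs sampling rate.
#' @return data frame with one row per (mode) giving mean self-calibrated and
#'   transferred overall accuracy (percent) over subjects 2..n, and the mean
#'   loss in percentage points.
#' @export
transferExperiment <- function(nSubjects = 20L, trialsPerClass = 5L, seed = 0L,
                               rmsSpread = 0.46, bandSpread = 0.43,
                               window = windowSpec(), fs = 1100) {
  stopifnot(nSubjects >= 2L)
  cohort <- makeCohort(nSubjects, rmsSpread, bandSpread, seed = seed)
  labels <- makeTrialLabels(trialsPerClass, trialsPerClass)
  out <- lapply(c("STFT_BAND", "RMS"), function(mode) {
    refCfg <- calibrateSubject(cohort[[1]], mode, window, fs = fs)
    selfAcc <- transAcc <- numeric(nSubjects - 1L)
    for (i in 2:nSubjects) {
      ownCfg <- calibrateSubject(cohort[[i]], mode, window, fs = fs)
      trace <- synthEpisode(reseedProfile(cohort[[i]], 2000L + i), labels,
                            fs = fs)
      acc <- function(cfg) {
        scored <- scoreEpisode(runController(trace, cfg, window)$events, labels)
        100 * mean(scored$correct)
      }
      selfAcc[i - 1L] <- acc(ownCfg)
      transAcc[i - 1L] <- acc(refCfg)
    }
    data.frame(mode = mode, self_pct = mean(selfAcc),
               transfer_pct = mean(transAcc),
               loss_pct = mean(selfAcc) - mean(transAcc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
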