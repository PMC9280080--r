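---
title: "Fixed-band spectral triggering for myoelectric control: models and methods"
author: "emgband"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Fixed-band spectral triggering for myoelectric control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single-degree-of-freedom assistive hand is opened and closed from two
surface-EMG channels placed over an antagonist muscle pair (wrist flexor and
extensor). The classical controller thresholds a time-domain amplitude
feature — the windowed RMS of the raw signal — at half of a per-user
calibration maximum. That works, but broadband amplitude is exactly what
powerline interference, electrode-motion artifacts and inter-subject gain
differences perturb, so RMS controllers need per-user, per-session threshold
calibration and are easily falsely triggered at rest.

The alternative implemented here monitors the mean spectral magnitude of a
fixed 60–80 Hz band, computed by a streaming 256-point short-time Fourier
transform (STFT) on a 1100 Hz stream. Muscle contraction concentrates sEMG
power between 30 and 200 Hz with its most prominent band near 70 Hz, while
the dominant contaminants live elsewhere: mains interference is a line at
50/60 Hz, motion artifacts sit below ~20 Hz, and broadband sensor noise
spreads its power over the whole Nyquist range so that little of it lands in
any one 20 Hz band. Thresholding the in-band magnitude therefore denoises
*implicitly* — no explicit filtering stage is needed — and the package
exists to make that claim testable end to end at desk scale: feature
extraction, STFT engine, trigger state machine, a synthetic sEMG generator
standing in for human recordings, and an evaluation harness.

## Signal model and containers

`SignalTrace` holds uniformly sampled multi-channel voltages in millivolts
with an explicit sampling rate; sample *i* (1-based) sits at
`t0 + (i − 1)/fs`. All analysis is windowed: a `WindowSpec` (length, hop,
taper) slides causally, a trailing partial window is discarded, and **a
frame is stamped with the time of its last sample**. The causal convention
matters: a feature is available only once its window has fully arrived, so
event timestamps are directly comparable to labelled onsets when measuring
detection latency.

CSV interchange uses a `time_s` column plus one `<channel>_mV` column per
channel; the sampling rate is inferred from the median timestamp increment
and the file is rejected if timestamps deviate from uniformity by more than
a relative 1e-6. WAV files are IEEE float32 with millivolts stored
unnormalised, so physical units survive a round trip; the header rate is
authoritative.

## Features

* `riemg` — rectified integrated EMG, `sum(|x|)/fs` (rectangular-rule
  integral): the envelope quantity integrated sEMG sensors report.
* `rmsAmplitude` — `sqrt(mean(x^2))`, the time-domain baseline feature.
* `psd` — tapered one-sided periodogram scaled so that
  `sum(power)·Δf` equals the mean square of the tapered window.
* `fmed` — median frequency. Each bin's power is treated as uniform across
  its width and the half-power crossing is located by linear interpolation
  inside the crossing bin; two equal bins at 60 and 80 Hz give exactly
  70 Hz. This removes bin-width quantisation.
* `fmean` — mean frequency, `Σ I·f / Σ I` with **linear magnitude**
  weights. Decibel weighting is available behind a flag but couples the
  value to an arbitrary reference level and breaks scale invariance, so it
  is not the default.
* `bandMagnitude` — the **mean** (not sum) of magnitudes over bins whose
  centre frequency lies in the closed interval [60, 80] Hz. The mean keeps
  the value insensitive to FFT length, so one threshold in mV transfers
  across window configurations. At 1100 Hz / 256 points the band covers
  bins 14–18 (60.16–77.34 Hz).

## STFT engine

`stft` applies a taper, FFTs each frame, and keeps the one-sided magnitude
with amplitude normalisation `2/Σg` (`1/Σg` at DC and Nyquist), so an
on-bin unit sinusoid reads ≈ 1 mV in its bin and thresholds are in input
units. Bin spacing is `fs/fftLen` = 4.297 Hz at the defaults.
`stftStreamer` consumes chunks of arbitrary size and emits each frame as
soon as its last sample arrives; for any chunking it reproduces the batch
result to better than 1e-12, which the tests assert as an equivalence
oracle.

The Hann taper is the default. Its first sidelobe at ±2.5 bins is −31 dB,
which bounds what a 50 Hz mains line (2.4 bins below the band's lowest bin
centre) can leak into 60–80 Hz. A rectangular taper is available to mimic a
bare microcontroller FFT. Note an honest geometric limitation: at this
grid, 60 Hz mains falls essentially *on* the band's edge bin (60.16 Hz), so
a 60 Hz mains environment genuinely intrudes into the trigger band and no
taper can prevent it; the synthetic generator therefore defaults to 50 Hz
mains, which is the out-of-band interference case the band-trigger
hypothesis addresses.

The hop is 64 samples (58.2 ms): the embedded configuration fixes
window and rate but not the hop, and 64 keeps the decision pipeline inside
a sub-350 ms recognition budget while overlapping frames by 75%.

## Trigger controller

Calibration sets each channel's threshold to `fraction × max(feature)` over
a whole calibration recording — the 50% rule, with the maximum read
literally rather than as a percentile. A series whose maximum does not
exceed 3× its median contains no contraction and is refused.

Classification is antagonist logic: FLEX when only the flexor channel
exceeds its threshold, EXT when only the extensor does, REST when neither;
when both exceed, the larger value/threshold ratio wins and an exact tie
keeps the previous state. Two mechanisms stabilise the state machine:

* **Feature smoothing** (`smoothFrames`, default 3): a causal trailing
  moving average of the per-frame feature. The raw band magnitude of a
  narrowband stochastic process is approximately a 5-bin mean of Rayleigh
  magnitudes and shows one-to-two-frame fades down to ~0.35× its plateau;
  without smoothing these fades split a substantial fraction of contraction
  trials into fragments. Three frames (116 ms) is the smallest average that
  removed fade-induced fragmentation in simulation while keeping the
  deterministic step-detection latency within (256 + 2·64)/1100 = 349 ms.
* **Hysteresis** (`releaseFraction`, default 0.6): an active state persists
  until its channel falls below 0.6× threshold. Because the calibration
  maximum of the (smoothed) band feature sits near 1.4–2× the contraction
  plateau, the 50% threshold lands close to the plateau mean; a release at
  0.8× threshold still chatters there, while 0.6 sits below the plateau's
  lower tail.

Debouncing (`debounceFrames`, default 1) commits a state change only after
the required number of consecutive agreeing frames. One motor command is
emitted per frame: `CLOSE_STEP` during FLEX, `OPEN_STEP` during EXT,
`HOLD` during REST. In RMS mode the same state machine runs on the windowed
RMS of the raw signal over the identical 256/64 grid, so the two modes are
comparable frame for frame.

## Synthetic sEMG generator

The generator emulates what the triggering problem needs and nothing more:

* **Contraction carrier.** White Gaussian noise shaped by an 8th-order
  Butterworth band-pass (30–200 Hz), a two-pole resonance at the subject's
  spectral peak (radius 0.95, ≈ 17 Hz bandwidth), and a second-order 80 Hz
  low-pass tilt reproducing the decaying high-frequency side of measured
  sEMG spectra. At the defaults the mean contraction periodogram peaks at
  the 68.75 Hz bin, holds ≈ 99% of its power in 30–200 Hz, and has a
  per-frame magnitude-weighted mean frequency of ≈ 70–71 Hz — matching the
  published per-subject feature statistics shipped in the fixture. A
  shallower band edge or a flat passband misses these targets: magnitude
  weighting is dominated by the filter's stop-band floor unless the edges
  are steep.
* **Two-component spectral split.** A second carrier carries out-of-band
  contraction energy (30–55 and 90–200 Hz, same tilt). The amplitude
  fraction of the narrowband component (`bandGain`, default 0.85) is a
  per-subject property. In a cohort, overall gain is drawn log-normally to
  hit a target RMS coefficient of variation (default 0.46), and `bandGain`
  co-varies with the same normal deviate so the band-magnitude CV hits its
  own target (default 0.43) — the two defaults are the CVs computed from
  the packaged fixture. This is a statistical device, not a physiological
  claim: it is the minimal mechanism that lets amplitude variability and
  in-band variability be dialled independently.
* **Envelopes.** Raised-cosine ramps of 100 ms between activation levels;
  the antagonist channel stays at rest plus a cross-talk fraction (default
  0.1) of the agonist's amplitude. Smooth, synchronous onsets make latency
  measurements well defined.
* **Resting baseline.** The same band-shaped process scaled to
  `restNoiseMv` (default 20 mV against a 400 mV contraction): resting sEMG
  occupies a similar band to contraction at low level. A white resting
  floor would make the in-band rest magnitude unrealistically small and any
  out-of-band leakage look proportionally enormous.
* **Artifacts.** Mains as a pure sinusoid (50 Hz default, see above);
  motion artifact as noise confined below its cutoff by a 4th-order
  low-pass (a 2nd-order filter leaks ≈ −22 dB of a 200 mV artifact into
  60–80 Hz, i.e. real in-band energy, defeating the purpose of modelling
  an out-of-band artifact); white broadband noise per channel. Powerline
  and motion terms are common mode across channels.
* **Determinism.** One integer seed fully determines an episode; cohort and
  episode seeds are derived arithmetically.

What the generator does **not** model: motor-unit action potential trains,
fatigue-induced spectral compression, electrode lift-off, impedance drift,
or any nonstationarity within a contraction. Passing tests on this
generator show that the pipeline behaves as designed under the stated
spectral and variability assumptions — not that those assumptions exhaust
real recordings.

## Evaluation harness

`makeTrialLabels` builds the standard protocol — alternating 2 s
contractions and 2 s rests, 20 flexions then 20 extensions (a 4 s movement
cadence). `cohortExperiment` calibrates each simulated subject on a clean
calibration episode, runs the controller on a fresh labelled episode, and
scores each labelled interval as a trial.

Scoring: a motion trial is correct when **exactly one** event of the
matching state covers ≥ 50% of it and no opposing active event covers more
than 25% of it; a rest trial is correct when no active event covers more
than 25% of it. The 25% slack is deliberate: detection and release latency
(window fill ≈ 233 ms plus smoothing) unavoidably spills ~0.3 s of each
event across trial boundaries, and a rule counting any overlap as a wrong
trigger would score every rest interval after a correct motion as an error.
The thresholds are fixed ahead of the experiments and are part of the
package's definition of "matched motion".

`variabilityReport` recovers across-subject feature dispersion (mean, SD,
CV, span) from per-subject contraction-level means, and
`table3Summary` reduces the packaged fixture of per-subject feature
statistics; the SD divisor (n vs n−1) is an explicit argument because
published summaries of this kind mix both conventions.

Problem sizes in the shipped tests and in `scripts/acceptance.R` — 20-seed
spectral checks, 20-episode artifact cohorts, a 20-subject × 40-trial
closed-loop cohort, 50 subjects for variability recovery — were chosen as
the smallest sizes at which the Monte-Carlo error is clearly below the
margins being asserted.

## Known limitations

* With the spreads estimated from the packaged fixture (RMS CV 0.46 vs
  band CV 0.43), threshold *transfer* between subjects degrades both modes
  almost identically in simulation: a relative 50%-of-max rule cannot
  distinguish two nearly equal relative spreads. The often-reported
  practical advantage of the fixed-band trigger — less per-user
  recalibration — rests on absolute voltage spans and on artifact
  robustness, which the simulations do reproduce, not on relative CVs.
  `transferExperiment` exposes the measurement; the tests assert only the
  band-mode bound (< 10 points lost), not a mode ordering.
* In a 60 Hz mains region the 60–80 Hz band must either be narrowed or the
  mains line notched; the band's lower edge bin collides with 60 Hz on the
  256-point grid.
* Accuracy figures from the synthetic cohort are not comparable to human
  trials: the generator has no intent variability, co-contraction, or
  fatigue.
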