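Package: emgband
Title: Fixed-Bandwidth Frequency-Domain Myoelectric Triggering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction, streaming short-time Fourier transform,
    threshold calibration and two-channel motion classification for
    surface-EMG (sEMG) driven assistive-device control. Implements a
    fixed-bandwidth (60-80 Hz) spectral-magnitude trigger alongside the
    classical RMS time-domain baseline, a labelled synthetic sEMG
    generator with powerline/motion/broadband artifact injection, and an
    evaluation harness that scores closed-loop flexion/extension/rest
    classification on synthetic cohorts and summarises packaged
    per-subject feature statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
Config/testthat/edition: 3
RoxygenNote: 7.3.3
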