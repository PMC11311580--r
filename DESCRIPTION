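Package: veressva
Title: Vibroacoustic Analysis of Veress Needle Insertion Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for vibroacoustic recordings of Veress
    needle insertions during laparoscopic access. Provides WAVE and
    annotation input/output, pre-processing (DC removal, spectral-gating
    noise reduction, Daubechies discrete-wavelet band filtering),
    extraction of 400 ms puncture-event segments with Morlet
    continuous-wavelet scalograms, excitation detection, six-phase
    segmentation of peritoneum-puncture events (friction, tissue
    breakage, click attack, fast and slow recovery, post-puncture
    settling), per-event energy/duration/latency/recovery metrics with
    cohort summaries, and a calibrated synthetic-signal generator with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
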