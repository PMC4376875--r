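Package: hybridbci
Title: Simulation and Offline Decoding of a Hybrid P300/SSVEP Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a visual brain-computer interface that
    superimposes an oddball (P300) stimulation on flickering (SSVEP)
    backgrounds. Provides a synthetic multichannel EEG generator emulating
    the paradigm's trial structure, standard electrophysiological
    preprocessing (mastoid referencing, zero-phase Butterworth filtering,
    epoching, peak-to-peak artifact rejection, decimation), target-ERP
    averaging and condition-pair correlation analysis, a linear
    support-vector-machine P300 decoder with repetition-averaged scoring
    and run-level cross-validation, SSVEP frequency detection by Minimum
    Energy Combination spatial filtering with harmonic signal-to-noise
    scoring (including a subject-trained harmonic-weighting variant), and
    hybrid decision fusion with accuracy and information-transfer-rate
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    kernlab,
    signal,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
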