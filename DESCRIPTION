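Package: trapcode
Title: Analysis Pipeline for Activity-Dependent Tagging Experiments in Auditory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing loose-patch electrophysiology and fluorescence
    histology from activity-dependent neuronal tagging (TRAP) experiments in
    auditory cortex. Covers construction of auditory playback schedules (pure
    tones, frequency-response-area grids, natural vocalizations with syllable
    time-reversal), spike detection from raw voltage traces, peri-stimulus time
    histogram response metrics (spontaneous and evoked rates, FWHM response
    windows, per-syllable significance, tuning parameters), d-prime stimulus
    discriminability matrices, linear-SVM pseudo-population decoding of
    vocalizations with cumulative syllable counts, and automated counting of
    fluorescently labeled nuclei with density fold-induction statistics. A
    synthetic-data module generates spike trains, voltage traces and
    fluorescence images with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
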