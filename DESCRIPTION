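Package: SpeechRhythm
Title: Diachronic Speech-Rhythm Analysis with Vocalic Interval Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal (diachronic) analysis of speech rhythm
    from interval-labelled recordings. Computes the percentage of vocalic
    duration over phonation time (%V) and the mean vowel-onset-to-vowel-onset
    interval (VtoV, the reciprocal of articulation rate) from Praat TextGrid
    annotations using a four-way vowel/consonant/disfluency/pause labelling
    scheme. Includes an incremental-window stabilization procedure to
    establish the minimum reliable sample duration, least-squares changepoint
    segmentation with pairwise t-tests for detecting step changes in a
    multi-year metric series, a calibrated synthetic-data generator
    (interval sequences, longitudinal corpora, and schematic audio), and a
    prototype acoustic segmenter that labels audio into vocalic, consonantal
    and silent intervals from frame-level energy, periodicity and spectral
    flatness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
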