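Package: imspeech
Title: Imagined-Speech EEG Classification with Pairwise SVM Voting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiclass classification of imagined words
    ("silent talk") from multichannel scalp EEG. Provides a synthetic EEG
    generator emulating a session/part/test acquisition design with
    class-dependent spectral signatures, record-to-record drift and artifacts;
    preprocessing (zero-phase low-pass filtering, block-average downsampling,
    sync-driven segmentation, energy-based artifact rejection); per-channel
    1 Hz-resolution normalized magnitude-spectrum features; a bank of pairwise
    linear support-vector machines combined by a majority rule with a
    specialist tie-break and an Unknown class; and Monte-Carlo cross-validated
    evaluation with accumulated confusion matrices under long-, short- and
    mixed-time classification modes.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
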