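Package: condpipe
Title: Analysis Pipeline for Paired CA1-Prefrontal Recordings During
    Appetitive Trace Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis chain for paired hippocampal-CA1 and
    prefrontal-cortex electrophysiology sessions recorded during appetitive
    auditory trace conditioning: lick-based learning classification,
    single-cell response taxonomy (evoked, trace-up/down, lick, reward),
    population rate-vector distance and trial-identity decoding,
    cross-area reduced-rank regression with cross-validated rank selection,
    multitaper LFP coherence with per-frequency permutation tests, awake
    sharp-wave-ripple detection, and ICA-based cell-assembly detection with
    Marcenko-Pastur thresholding and ripple-triggered reactivation analysis.
    Includes a synthetic-session generator with ground truth so every stage
    is testable without recorded data.
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
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
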