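Package: beatfuse
Title: Beat-Level Attention Fusion Networks for Multilabel 12-Lead ECG
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilabel arrhythmia classification from 12-lead
    electrocardiograms by segmenting each record into heartbeats at detected
    R-peaks, encoding every beat with a shared one-dimensional convolutional
    and bidirectional gated-recurrent-unit encoder, fusing the per-beat
    features with a masked attention mechanism, and classifying with a
    sigmoid multilabel head.  Includes a Pan-Tompkins R-peak detector
    adapted to 100 Hz, a seeded synthetic ECG generator with known R-peak
    ground truth for end-to-end testing, rank-based (Mann-Whitney) AUC
    metrics with macro averaging, an Adam training loop with
    cross-validation ensembling, ablation variants of the architecture, and
    an optional loader for the PTB-XL database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
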