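Package: oscdecode
Title: Dissociating Oscillatory and Non-Oscillatory Stimulus Information in
    Epoched Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose epoched multichannel electrophysiological
    recordings (trials x channels x time arrays) into an uncorrelated slow
    non-oscillatory trend and a theta-band oscillatory residual, and to
    dissect where time-resolved decoding accuracy comes from.  Implements
    temporal generalization matrices (TGMs) with nested cross-validated
    ridge decoders, a constrained left-to-right decoder-sequence model
    (temporally unconstrained decoding) with per-trial state time courses,
    phase-locking factor (PLF) statistics on decoder-aligned windows, and
    permutation tests with non-parametric combination that dissociate
    global latency shifts from relative cross-channel phase effects.  A
    synthetic-data generator with recorded ground truth exercises the full
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
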