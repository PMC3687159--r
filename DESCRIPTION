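Package: cascann
Title: Structurally Constrained Neural Network Models of Three-Layer
    Transcriptional Regulatory Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models three-layer transcriptional regulatory cascades
    (upper-layer transcription factors regulating module-level
    transcription factors regulating a target gene) as feed-forward
    neural networks whose connectivity is masked to match the biological
    wiring. Includes GRAM-style discovery of co-bound, co-expressed gene
    modules from expression and binding p-value data, cascade
    construction with a promoter binding-site filter, Levenberg-Marquardt
    training with validation-based early stopping, a repeated
    train/validation/test evaluation protocol scored by Pearson
    correlation, search over per-regulator backward time shifts for
    asynchronous regulation, heterodimer augmentation of single-regulator
    modules with degree-matched random controls, output-shuffle
    significance testing, and a synthetic data generator that emulates
    the full input bundle from a planted ground-truth cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
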