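Package: tearbreakup
Title: Tear-Film Breakup Detection on Interference Color Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive, objective detection of tear-film breakup in
    lipid-layer interference color images. Provides a physics-based
    synthetic image generator (two-beam thin-film interference rendering
    of a lipid thickness field, breakup morphologies and imaging
    confounders), a nine-class 96x96 patch classifier built as a frozen
    convolutional feature extractor plus a trainable softmax head,
    an overlapping-tile frame-level decision rule, video-grouped six-fold
    cross-validation, and ROC/AUC evaluation with confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
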