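Package: germquant
Title: Quantification of Germ Cell Proliferation and Apoptosis in Testis
    Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify germ-cell proliferation and apoptosis in
    mouse testis histology. Implements a dual-channel immunofluorescence
    pipeline (Otsu thresholding of the TRA98 germ-cell channel, removal of
    border-touching nuclei, watershed separation of touching nuclei,
    per-nucleus KI-67 intensity and coverage features, and a
    ridge-stabilized logistic-regression KI-67 classifier), a seeded
    synthetic fluorescence-field generator with exact per-nucleus ground
    truth for validation, and the counting statistics used for seminiferous
    tubule cross-sections (oblique-section diameter-equivalent counting,
    per-tubule means with unpaired t-tests, pooled apoptotic-tubule
    frequencies with chi-square tests, and Mendelian goodness-of-fit).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
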