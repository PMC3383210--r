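Package: opsqsar
Title: PLS-QSAR Modelling with Ordered Predictors Selection and Full
    Validation Battery
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partial-least-squares (NIPALS PLS1) regression for
    quantitative structure-activity relationship (QSAR) modelling, with
    Ordered Predictors Selection (OPS) variable selection and the standard
    chemometric validation battery: leave-one-out and leave-N-out cross
    validation, y-randomization with Eriksson intercept criteria,
    hierarchical-clustering-aided train/test splitting, external
    validation metrics (R2pred, SEP, Golbraikh-Tropsha slopes), and
    leverage/studentized-residual outlier diagnostics.  Ships a worked
    data set of 31 cinnamoyl pyrrolidine MMP-2 inhibitors and a seeded
    synthetic descriptor-matrix generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
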