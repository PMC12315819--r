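Package: dualspot
Title: Dual-Channel Fluorescent Particle Detection and Co-Aggregate Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-based co-localization analysis for surface immunoassays
    that count protein co-aggregates as overlapping fluorescent particles in
    paired red/far-red microscopy images. Provides a synthetic dual-channel
    field generator with known ground truth, histogram-equalization image
    enhancement, contour- and Hough-circle particle detection, one-to-one
    spot matching with a chance-overlap correction under complete spatial
    randomness, well-level aggregation with dilution-linearity and batch QC
    rules, cohort biomarker statistics (t-test, one-way ANOVA with Tukey,
    bootstrap ROC/AUC, Spearman correlation), and 1:1 Langmuir binding
    kinetics utilities for surface plasmon resonance sensorgrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    igraph,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
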