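Package: maptrace
Title: Lysosome Trafficking, Microtubule Proteomics, Laminar Distribution and qPCR Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for a tubulinopathy mouse model study
    design: kymograph-based lysosome trafficking quantification (run segmentation,
    movement classification, retrograde transport metrics), paired TMT
    microtubule-co-sedimentation differential proteomics with an empirical-Bayes
    moderated paired t-test and a candidate microtubule-associated-protein filter
    cascade, binned laminar cell-distribution statistics with a two-way mixed
    ANOVA, and efficiency-corrected qPCR relative quantification against the
    geometric mean of reference genes. Includes seeded synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
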