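Package: ailqtl
Title: QTL Mapping in Advanced Intercross Lines with Resampling-Based
    Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and linkage analysis of advanced intercross line
    (AIL) crosses for quantitative and binary disease traits. Implements
    Haley-Knott regression and binary (logistic) single-QTL genome-region
    scans on conditional genotype probabilities with AIL map expansion,
    family-residual significance thresholds, 1.5-LOD support intervals, a
    two-QTL drop-term fit model, bootstrap QTL localization probabilities,
    allelic-effect classification (dominance, heterosis, transgressive
    segregation), genotype-matched congenic phenotype prediction, and
    delta-delta-Ct relative quantification of qPCR expression data. A
    configurable G10 AIL simulator provides synthetic cohorts with the
    family structure the threshold procedure assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
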