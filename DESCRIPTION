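Package: ExoScreen
Title: Growth and Exometabolome Analysis of Nutrient-Supplementation
    Screens in Cyanobacteria
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput nutrient-supplementation
    screens of phototrophs profiled by optical density and untargeted
    negative-mode LC-MS exometabolomics. Classifies per-condition growth
    effects against an unsupplemented control (Welch's t test on final
    OD750), annotates ions by exact mass with isobar collapsing, normalizes
    exometabolome feature tables against background medium with
    limit-of-detection thresholding and supplement masking, calls
    mixotrophic substrate drawdown, ranks exuded metabolites, scores
    metabolic pathway representation per condition, and profiles conditions
    by PCA of normalized exudate signatures. Includes a seeded synthetic
    screen generator with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, MassSpectrometry, Normalization, Software
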