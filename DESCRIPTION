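Package: ffpescreen
Title: Genome-Wide Survival Screening of RNA-Seq Counts from Archival Tumor Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for RNA-seq biomarker screening in archival
    (FFPE) tumor cohorts with time-to-event follow-up. Implements third-quartile
    normalization of raw count matrices, feature-vectorized univariate Cox
    proportional-hazards screening with the Lin-Wei robust sandwich variance,
    Storey q-value false discovery rates, true-discovery degree-of-association
    (TDRDA) effect-size sets, regression-to-the-mean corrected standardized
    hazard ratios, a pooled read-island algorithm for discovering transcribed
    intergenic regions, thresholded co-expression networks, estrogen-receptor
    status calling from marker expression, and cross-platform concordance
    statistics. A synthetic-cohort generator reproduces the statistical
    structure the analysis assumes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
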