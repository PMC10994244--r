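Package: mesoprofiler
Title: Copy-Number, Splicing and CDK4-Activity Profiling for Mesothelioma Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy pipeline for the bespoke computations used to profile
    pleural mesothelioma samples: purity- and ploidy-aware copy-number
    calling from the off-target reads of a targeted capture panel
    (binning, circular binary segmentation, grid fit of the ratio model
    r = (nT*rho + 2(1-rho))/psi), a per-exon expected-splicing-ratio
    detector for RB1 disruption from RNA-seq alignments, classification
    of CDK4 Thr172-phosphorylation profiles from 2D-gel spot volumes
    with a proliferation-score correlate, and expression-side plumbing
    (CP20M normalization, gene and viral-count thresholds, marker-gene
    stratification, Kaplan-Meier / Mantel-Cox survival comparison).
    Ships seeded synthetic-data generators with exact ground truth so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
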