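Package: rrbsclock
Title: Construction, Application and Comparison of RRBS-Based DNA
    Methylation Age Clocks
Version: 0.1.0
Authors@R:
    person("Methylation Clock", "Maintainers", email = "maintainers@rrbsclock.org",
           role = c("aut", "cre"))
Description: Toolkit for building and exercising DNA-methylation age
    predictors ("epigenetic clocks") from reduced representation bisulfite
    sequencing (RRBS) data. Reads bismark coverage files and clock
    definition tables, applies coverage-based sample and site quality
    filters for whole-lifespan multi-tissue clocks, trains linear clocks
    by elastic-net regression with tissue-stratified cross-validation
    (coordinate descent implemented in compiled code), applies any clock
    definition with explicit missing-site policies and age transforms,
    and provides a statistical battery for comparing clocks and detecting
    lifespan-intervention effects: exact and normal-approximation
    Mann-Whitney U tests, residual-slope regression diagnostics,
    slope/intercept group comparisons, delta-age correlation analysis,
    weight-distribution symmetry and variance tests, Yates-corrected
    chi-square overlap tests, CpG island/shore/shelf annotation, and a
    resampling-based clock-site robustness analysis. A bundled synthetic
    methylome simulator generates age-structured RRBS cohorts
    (age-drifting CpG methylation, binomial read noise, tissue and batch
    effects, site dropout) so the entire pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
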