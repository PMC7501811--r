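Package: magicmet
Title: Genotype-by-Environment and Phenotypic Plasticity Analysis for
    Multi-Parent Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-environment trials (MET) of
    8-founder multi-parent advanced generation intercross (MAGIC)
    populations. Provides within-environment spatial correction of
    greenhouse row/position heterogeneity by mixed models, REML variance
    decomposition with per-environment residual variances (broad-sense
    heritability and the proportion of genotype-by-environment variance),
    Finlay-Wilkinson joint regression and factorial regression on
    environmental covariates (slope, non-linear plasticity variance, and
    covariate sensitivity), Haley-Knott regression QTL scans on founder
    haplotype probabilities with genome-wide thresholds, peak calling and
    1-LOD confidence intervals, a two-step forward-backward procedure for
    QTL-by-environment interaction detection with permutation thresholds,
    and cross-result synthesis (environment clustering, QTL category
    overlap, chromosome enrichment, allelic-effect concordance, and
    selective-sweep intersection). A synthetic MAGIC-MET generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
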