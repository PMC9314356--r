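Package: polyresilience
Title: Polygenic Resilience Scores for Late-Onset Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tested pipeline for deriving and evaluating polygenic resilience
    scores in late-onset Alzheimer's disease case-control cohorts. Identifies
    unaffected individuals at the highest polygenic risk, contrasts them with
    risk-matched cases in a resilience GWAS, removes risk-associated variants
    and their linkage-disequilibrium partners, clumps the remaining marginal
    variants, and evaluates risk-orthogonal resilience scores across P-value
    thresholds with inverse-variance random-effects meta-analysis, genomic
    control, Nagelkerke pseudo-R2 and liability-scale conversion. Includes a
    liability-threshold simulator of multi-study cohorts with an APOE-e4-like
    major-effect locus and conditionally protective resilience variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
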