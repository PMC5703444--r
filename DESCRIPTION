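Package: cortwin
Title: Twin Modelling and Polygenic Score Analysis of Hair Cortisol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the heritability of hair cortisol
    concentration (HCC) and its genetic overlap with perceived stress,
    depressive symptoms, and neuroticism in twin cohorts. Provides a
    synthetic twin-family data generator with known ground truth
    (Cholesky-structured latent traits, graded-response questionnaire
    items, log-normal hair cortisol with experimental batch effects,
    Mendelian genotypes and a simulated discovery GWAS); phenotype
    preparation (log transformation, winsorization, covariate
    residualization, item response theory calibration and scoring,
    z-score harmonization); multivariate Cholesky ACE/AE/CE twin models
    fitted by full-information maximum likelihood with likelihood-ratio
    model selection, profile-likelihood confidence intervals, and
    median age-split reanalysis; a polygenic risk score pipeline
    (genotype quality control, allele harmonization, LD clumping,
    multi-threshold scoring, ancestry principal components, pedigree
    kinship, and family-aware mixed-model association with one-sided
    tests); and descriptive report assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
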