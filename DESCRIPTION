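Package: kidneycca
Title: Multivariate SNP Discovery for Kidney Function by Canonical
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-SNP canonical correlation analysis (CCA) of genotype
    dosages against two kidney-function markers (eGFR and BUN), both from
    individual-level cohorts and from univariate GWAS summary statistics
    (the metaCCA construction), with the surrounding discovery pipeline:
    genotype quality control and phenotype standardisation, Wilks' Lambda
    significance testing, effect-direction filtering, cross-dataset
    harmonisation and replication, greedy lead-SNP clumping with
    nearest-gene annotation, approximate-Bayes-factor eQTL colocalisation,
    hypergeometric set-overlap enrichment, differential-expression and
    case-versus-population allele-frequency follow-up, and a synthetic
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
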