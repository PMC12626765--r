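Package: mrcascade
Title: Two-Step Mendelian Randomization Screening and Mediation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) mediation
    studies built on GWAS summary statistics: instrument selection with
    explicit variance-explained and F-statistic formulas, LD clumping
    against a precomputed pairwise r-squared table, allele harmonization
    with palindromic-variant resolution, five causal estimators (IVW,
    MR-Egger, weighted median, simple and weighted mode) with a
    sensitivity battery (Cochran's Q, Egger intercept, cross-method
    direction consistency, reverse MR), a multi-stage exposure-mediator-
    outcome screening cascade with full audit trails, and product-of-
    coefficients mediation with delta-method intervals. A seeded
    synthetic GWAS generator with a known causal triad structure makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, grDevices, graphics, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'sumstats-io.R'
    'ld.R'
    'instrument-selection.R'
    'harmonization.R'
    'mr-estimators.R'
    'mr-battery.R'
    'mediation.R'
    'cascade.R'
    'simulate.R'
    'reporting.R'
    'pipeline-run.R'
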