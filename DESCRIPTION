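Package: protmr
Title: Proteome-Wide Mendelian Randomization and Colocalization Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scanning circulating-protein exposures against disease
    outcomes with two-sample Mendelian randomization from GWAS summary
    statistics. Covers cis-pQTL instrument selection (p-value, minor-allele
    frequency and weak-instrument F filters, greedy LD clumping within a
    cis window), effect-allele harmonization with frequency-based resolution
    of palindromic variants, Wald-ratio and inverse-variance-weighted causal
    estimation with Cochran's Q and MR-Egger sensitivity analyses, Bayesian
    colocalization over the five single-causal-variant hypotheses via
    approximate Bayes factors, and annotation of prioritized proteins with
    druggable-genome tiers and therapeutic-target development phases. A
    summary-statistics simulator with known ground truth supports calibration
    and power checks of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
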