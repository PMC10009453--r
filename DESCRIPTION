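Package: revmr
Title: Reverse Mendelian Randomization of Disease Liability on Metabolic Trait Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample reverse Mendelian randomization (MR) toolkit for
    estimating effects of genetic liability to binary diseases on panels of
    continuous traits from GWAS summary statistics. Covers instrument
    selection and LD pruning, allele harmonisation (strand flips and
    palindromic variants), inverse-variance-weighted, MR-Egger, weighted
    median and weighted mode estimators with per-doubling-of-liability
    scaling, radial-MR outlier detection, multivariable MR for correlated
    liabilities, age-stratified estimation with cross-stratum contrasts,
    a correlated-trait effective-tests multiplicity threshold, and a
    synthetic GWAS summary-statistics generator for validating every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
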