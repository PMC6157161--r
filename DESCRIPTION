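Package: qltdt
Title: Quasi-Likelihood Transmission-Based Association Tests for
    Longitudinal Quantitative Traits in Nuclear Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based association testing for multivariate and
    longitudinal quantitative phenotypes via a quasi-likelihood
    (estimating-equation) model of parental minor-allele transmission
    conditional on offspring phenotype, with a k-degree-of-freedom Wald
    test.  Includes pedigree/VCF/phenotype ingestion, EM imputation of
    multivariate-normal missing phenotypes, covariate adjustment,
    principal-component phenotype construction, variant and family
    filtering, a genome scan with Benjamini-Hochberg FDR control, and a
    synthetic nuclear-family data generator for calibration and power
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
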