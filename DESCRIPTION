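Package: mrkit
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization on GWAS summary
    statistics: instrument selection at a genome-wide significance threshold,
    LD-proxy substitution from a user-supplied linkage table, allele
    harmonization with palindromic-variant handling, causal estimation by
    Wald ratio, inverse-variance weighting, MR-Egger regression, weighted
    median and mode-based estimators, the MR-PRESSO resampling outlier test,
    heterogeneity/pleiotropy/influence diagnostics, and closed-form
    non-centrality-parameter power analysis for binary outcomes. Includes a
    synthetic summary-statistics generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
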