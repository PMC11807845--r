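Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening many exposures against one outcome with
    two-sample Mendelian randomization from GWAS summary statistics:
    instrument selection by p-value with greedy LD clumping and
    F-statistic strength filtering, allele harmonization with palindromic
    variant removal, five causal estimators (inverse-variance weighted,
    MR-Egger, simple mode, weighted median, weighted mode), heterogeneity
    (Cochran's Q), horizontal-pleiotropy (Egger intercept) and
    leave-one-out sensitivity diagnostics, an odds-ratio
    direction-consistency screen, a reverse-causation stage, and a
    synthetic summary-statistics generator with known causal structure
    for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
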