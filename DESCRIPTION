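Package: pwmr
Title: Proteome-Wide Mendelian Randomization for Plasma-Protein Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for proteome-wide two-sample Mendelian
    randomization with cis-pQTL instruments: summary-statistics harmonization,
    instrument selection (genome-wide significance, LD clumping, cis windows,
    MHC exclusion, F-statistic filtering), Wald-ratio and inverse-variance
    weighted causal estimation with heterogeneity, pleiotropy, MR-PRESSO and
    Steiger diagnostics, summary-data-based MR with the HEIDI linkage test,
    Bayesian colocalization over five hypotheses, two-step mediation analysis
    with delta-method intervals and the Sobel test, evidence tiering, and a
    synthetic GWAS summary-statistics generator with known ground truth for
    end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
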