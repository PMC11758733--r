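Package: steromr
Title: Two-Sample Mendelian Randomization for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-sample Mendelian randomization from GWAS
    summary statistics: instrument selection (p-value filtering, greedy LD
    clumping, confounder exclusion, F-statistic screening), allele
    harmonization with strand-flip resolution and palindromic-SNP handling,
    three causal estimators (inverse-variance weighted, MR-Egger, weighted
    median), sensitivity diagnostics (Cochran's Q, MR-Egger intercept test,
    MR-PRESSO global/outlier/distortion tests, leave-one-out), a grid runner
    over exposure-outcome pairs with Bonferroni-based significance labelling,
    and a seeded synthetic summary-statistic generator with known causal
    effect, pleiotropy regime, LD blocks and injectable outliers for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
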