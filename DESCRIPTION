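Package: cnvconcord
Title: Case-Control Association and Cross-Platform Concordance Analysis of
    Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quality assessment of SNP-array derived copy number
    variant (CNV) calls in case-control cohorts: marker-count and segment-size
    call filtering, allelic association statistics (odds ratio with Woolf
    confidence interval, Pearson chi-squared and exact hypergeometric tests),
    an array-versus-MLPA match-score concordance framework with per-locus
    validation summaries, call-reliability curves as a function of median
    segment size and marker count, and linkage-disequilibrium region screening
    of CNVs at candidate susceptibility loci. Includes a seeded synthetic
    cohort generator (Hardy-Weinberg genotypes, odds-ratio parameterised
    case-control differences, marker-count dependent miscall process, batch
    effects, near-truth MLPA observations) so every stage is testable without
    access to raw array data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
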