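Package: bonematch
Title: Forensic Genotype Matching and Compliance Auditing for Wildlife
    Skeleton Export Quotas
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing compliance of quota-regulated wildlife
    skeleton exports with forensic genetics. Implements mitochondrial SNP
    species assignment with a supervised two-species admixture estimator,
    microsatellite marker validation statistics (polymorphic information
    content, probability of identity, exclusion probabilities, exact
    Hardy-Weinberg and linkage-disequilibrium tests, genotype accumulation
    curves), Queller-Goodnight pairwise relatedness with generalized
    extreme studentized deviate significance for farm-to-port sample
    matching, duplicate-skeleton detection, paired skeleton-weight audits
    with consignment regressions, and a synthetic cohort generator with
    planted anomalies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
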