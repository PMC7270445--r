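Package: vitdgrs
Title: Vitamin D Genetic Risk Scores and Newborn Anthropometry in Pregnancy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for studying maternal vitamin D status with a
    genetic approach in mother-infant cohorts. Builds unweighted genetic risk
    scores (total, synthesis and metabolism) from a six-SNP vitamin D panel,
    runs per-SNP quality control (minor allele frequency, Hardy-Weinberg
    equilibrium), classifies maternal 25-hydroxyvitamin D status (IOM
    cut-offs) and newborn anthropometry (WHO cut-offs), and fits
    covariate-adjusted association and gene-environment interaction models
    with Bonferroni multiple-testing accounting. Includes a seeded synthetic
    cohort generator emulating the enrolment, dropout and DNA-yield exclusion
    flow of a prospective pregnancy cohort so the full pipeline is testable
    without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml,
    withr,
    rlang,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
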