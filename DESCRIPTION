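Package: pgxselect
Title: Patient Selection for Pharmacogenomic Testing from Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying health-plan members most likely to benefit
    from preemptive pharmacogenomic (PGx) testing using pharmacy and medical
    claims. Implements two ranking strategies over a configurable drug-gene
    knowledge base: a manual medication-count method and an automated
    pharmacogenetic interaction probability (PIP) score that models
    phenotype prevalence and phenoconversion by co-medications. Includes
    claims ingestion with NDC-to-ingredient mapping and eligibility
    filtering, natural-cut cohort selection against a testing budget,
    two-cohort comparison statistics, and a seeded synthetic claims
    generator calibrated to published medication-usage marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    ggplot2
VignetteBuilder: knitr
Config/testthat/edition: 3
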