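Package: nahrtwin
Title: Sperm NAHR Deletion-Rate Estimation, Twin Heritability and
    Paternal-Age Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies nonallelic homologous recombination (NAHR)
    deletion rates in sperm from small-pool PCR limiting-dilution data
    (Poisson occupancy correction with exact chi-square confidence
    intervals), estimates the heritability of deletion rate in
    monozygotic co-twins via one-way intraclass correlation with an
    unrelated-pair resampling null, models germline genome replications
    as a function of paternal age, simulates power to detect linear and
    logit-logistic paternal-age effects, and screens candidate
    covariates (PRDM9 class, BMI, smoking, alcohol, SNP dosages,
    paralog sequence identity). Includes a synthetic cohort generator
    with tunable heritability, age effect and assay depth, and a
    pipeline driver producing a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
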