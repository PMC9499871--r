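Package: strainflow
Title: Strain-Level Tracking and Outcome Prediction for Fecal Microbiota
    Transplantation Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track conspecific microbial strain populations across
    donor, recipient-baseline and post-intervention fecal metagenomes. Reads
    per-species SNV allele-count and gene-cluster coverage tables, applies
    species-detection, SNV-retention, gene-presence and extended-core rules,
    computes strain population diversity (inverse-Simpson based) and allele
    distances between samples, scores per-species transplantation outcomes
    (donor colonization, recipient persistence, coexistence, novel-strain
    influx, rejection, loss) from determinant alleles, aggregates cohort-level
    colonization and persistence indices, generates stratified shuffled-triad
    null cohorts, and predicts outcomes with repeated cross-validated
    LASSO-regularized regression. Includes a seeded synthetic strain-mixture
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
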