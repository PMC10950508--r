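Package: pgxddi
Title: Pharmacogenomic Landscapes, Population Differentiation and
    Binary-Vector Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for population-scale pharmacogenomic profiling of
    drug lists: per-drug risk-variant carriage summaries over a genotyped
    cohort, cross-population allele-frequency comparison by Fisher's exact
    test, pairwise weighted Weir-Cockerham Fst, a deleteriousness filter
    for candidate variants (nonsynonymous, at least 2 of 3 predictor votes,
    cohort allele frequency above threshold), and a drug-drug interaction
    (DDI) predictive model based on Russell-Rao similarity of binary
    carrier/transporter/enzyme/target (CTET) vectors, with regimen-level
    DDI counting and drug-gene bipartite network export. Includes a
    synthetic-data module (Balding-Nichols genotypes, planted CTET
    catalogs, clinical-annotation and diplotype tables) with full ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
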