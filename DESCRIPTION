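Package: melanoseek
Title: Disease-Based Drug Repurposing for Cutaneous Malignant Melanoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for disease-based drug repurposing in
    cutaneous malignant melanoma. Harmonizes gene-disease evidence from five
    sources (GWAS, PheWAS, metabolomics, transcriptomics, biomedical disease-gene
    tables) into per-gene provenance profiles, reconstructs the bipartite
    metabolite-protein network, maps the unified gene set onto approved
    drug-target records, excludes drugs with known melanoma indications, applies
    a gain-/loss-of-function versus drug-action concordance filter, and scores
    the surviving candidates against ranked drug-response expression signatures
    with a Kolmogorov-Smirnov tag enrichment statistic and anchor-oriented
    connectivity selection. Ships a synthetic-data generator with planted ground
    truth so the entire cascade is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
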