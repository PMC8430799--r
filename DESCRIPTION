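Package: mirhub
Title: MicroRNA-Target Interaction Networks, Hub Ranking and Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite microRNA-mRNA target interaction networks from
    multi-database prediction tables (miRDB-like, mirSVR-like and curated
    dialects) with score-based inclusion thresholds, ranks target genes by
    node degree and extracts hub neighborhoods. Supports the downstream
    validation workflow around such networks: cross-species mature-miRNA
    homology matching by exact global alignment with seed-sequence
    comparison, relative qPCR quantification by the 2^-ddCp method with
    one-way ANOVA and Dunnett many-to-one post-hoc testing, and gene
    ontology style overrepresentation analysis with hypergeometric tests
    and Bonferroni correction. Includes seeded synthetic-data generators
    with planted structure for benchmarking every stage, and a pipeline
    orchestrator producing a machine-readable report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    mvtnorm,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
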