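Package: oncopath
Title: Cancer-Type-Specific Pathways and Drug Repurposing from Multi-Omics
    Cell-Line Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies transcripts and proteins characteristic of individual
    cancer types from cell-line expression profiles (one-vs-rest t tests with
    an FDR-grid / clustering Gini-purity cutoff selection), calls biological
    pathways enriched in each significant feature set (one-sided Fisher exact
    test with Benjamini-Hochberg correction and a permutation bootstrap),
    combines transcript- and protein-level evidence into a single significance
    score, links drugs to cancer types through multi-pathway target genes, and
    validates predictions with drug-sensitivity (mnAUC) comparisons and a
    randomized hit-rate test.  Includes a seeded synthetic-study generator with
    planted ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
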