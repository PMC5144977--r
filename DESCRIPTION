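Package: gwsets
Title: Annotation and Gene-Set Enrichment Analysis of Genome-Wide Study Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an embedded single-file SQLite knowledge base of SNP
    positions, gene spans and gene-set (pathway) membership, and annotates
    genome-wide association (GWAS) and expression (GWES) results against it.
    Provides bidirectional SNP-to-gene mapping with flexible, strand-aware
    gene boundaries, gene-to-gene-set mapping and region queries; aggregates
    per-SNP association p-values into gene-level effect measures (minimum p,
    second-smallest p, Simes' combination, Fisher's combination) and rescales
    any gene measure to midrank uniform scores (U-scores); and tests gene-set
    over-representation with hypergeometric exact tests for candidate gene
    lists (CGEA) and for top-ranked U-score genes (USGSA), with min-p
    permutation adjustment and a pregenerated null table for fast adjusted
    p-values. Includes a seeded generator of toy annotation stores and study
    results with planted enriched pathways for validation, and a command-line
    interface over every operation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
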