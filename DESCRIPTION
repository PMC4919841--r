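Package: proteocat
Title: Iterative Metaproteomic Identification and Quantification Against
    Microbial Gene Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained metaproteomics pipeline for shotgun MS/MS data
    searched against large microbial gene-catalog protein databases. Implements
    an iterative two-step peptide-spectrum search (a loose target-only pass
    reduces the catalog to a sample-specific database; a second target-decoy
    pass yields FDR-controlled identifications), construction of a combined
    non-redundant study database, hyperscore/expect-value scoring of b/y
    fragment ladders, subset-rule protein grouping with razor peptides,
    MaxLFQ-style label-free protein quantification with match-between-runs,
    COG functional roll-up, unique-peptide lowest-common-ancestor taxonomy,
    and two-group comparison statistics. Ships a seeded synthetic-study
    generator (catalog, taxonomy, annotations, MGF spectra with ground truth)
    so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
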