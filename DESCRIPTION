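Package: genevidence
Title: Ranking Gene-Disease Evidence Sentences and Disease Relationships
    from Annotated Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based gene-disease discovery downstream of
    named-entity and event recognition. Assembles gene-event-disease evidence
    triples from annotated sentence corpora, ranks evidence sentences with a
    naive Bayes classifier and sigmoid-normalized scores, expands
    disease-related keyword lists by word-embedding analogies, aggregates
    evidence into per-disease gene rankings under five measures, compares
    ranked genes against reference gene sets (GMT), and analyses
    disease-disease relationships via gene-set overlap, protein-interaction
    network separation, and GO-annotation similarity. Includes seeded
    synthetic-data generators for every input so the full pipeline is
    testable without external downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
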