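Package: coldref
Title: Post-Assembly Transcriptome Clustering, Tiered Annotation and
    Tissue Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the post-assembly stages of a de novo
    transcriptome study: length filtering and redundancy clustering of
    assembled contigs with longest-representative selection, tiered
    best-hit database annotation with cascade accounting, Gene Ontology
    assignment from accession mappings with GO-slim projection over the
    ontology DAG, per-term incidence comparisons between transcriptomes
    (chi-square and exact Fisher tests with Benjamini-Hochberg
    correction) and hypergeometric term enrichment, Illumina read
    cleaning, library-size count normalization, low-expression
    filtering, and tissue expression-profile partitioning. A
    synthetic-data generator with planted ground truth produces every
    input the pipeline consumes, so all stages are testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
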