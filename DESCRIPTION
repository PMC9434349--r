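Package: disnet
Title: Gene-Based Disease Similarity Networks and Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted disease-disease similarity networks from curated
    gene-disease association tables, with edge weights given by the Jaccard
    index between per-disease gene sets. Detects disease communities by
    weighted-modularity optimisation using an in-package implementation of the
    Leiden algorithm (local moving, refinement, aggregation), backed by an
    exhaustive-partition oracle for small graphs. Decomposes community gene
    sets into unions, cross-community overlaps and community-exclusive genes,
    tests exclusive gene sets for pathway over-representation (hypergeometric
    test with Benjamini-Hochberg FDR control), and maps rare de novo
    loss-of-function variants onto community gene sets. Includes a synthetic
    data generator with planted community structure, planted enriched pathways
    and planted recurrently mutated genes so the whole pipeline is testable
    without licensed data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
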