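Package: ontosim
Title: Knowledge-Based Semantic Similarity and Relatedness for Concept
    Taxonomies
Version: 0.1.0
Authors@R:
    person("Ontosim", "Developers", email = "ontosim@example.org",
           role = c("aut", "cre"))
Description: Computes knowledge-based semantic similarity and relatedness
    between concepts in a taxonomy or semantic network. Parses concept
    graphs from edge-list, OBO 1.2 and pipe-delimited (RRF-style)
    relationship files, derives a rooted acyclic taxonomy with cached
    depth, leaf-count and subsumer-count statistics, and implements
    path-finding measures (Path, scaled Leacock-Chodorow, Wu-Palmer),
    information-content measures (Lin, Jiang-Conrath distance and its
    unit-interval LCH/Path reformulations) under intrinsic or corpus IC,
    and personalized-PageRank cosine relatedness over taxonomy-only or
    all-relationship graphs. Includes benchmark evaluation via Spearman
    rank correlation and Fisher r-to-z tests, seeded random-DAG fixtures
    and independent brute-force oracles, and an 'ontosim' command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
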