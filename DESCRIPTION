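Package: vegnet
Title: Bipartite Species-Transect Networks and Community Cliques for
    Vegetation Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite species-transect co-occurrence networks from
    line-transect vegetation survey tables, partitions them into community
    "cliques" (greedy modularity agglomeration and MCODE
    neighbourhood-density clustering), identifies hub species, and
    superimposes the clique memberships of two focal invasive plants across
    sites to classify their native partners as shared or exclusive (with
    Markov clustering of the combined association graph). Supporting
    ecological statistics include rank abundance, analytic rarefaction,
    Bray-Curtis dissimilarity with UPGMA dendrograms, and the Pearson test
    for abundance-level exclusion between invaders. A seeded synthetic
    survey generator with planted co-occurrence blocks and mutually
    exclusive focal invaders supports end-to-end recovery experiments.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
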