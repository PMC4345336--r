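Package: nlcomm
Title: Hybrid Node-Link Community Detection in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects node communities, link communities, and hybrid
    mixtures of both in undirected (optionally weighted) networks using a
    probabilistic degree-allocation model: each community is a
    degree-corrected random graph, and every node splits its observed
    degree across communities. The model is fitted either by an
    expectation-maximization algorithm for the Poisson likelihood or by
    symmetric nonnegative matrix factorization with a degree-constraint
    penalty. The type of each community (node or link) is selected by
    minimizing a generalized two-level map equation (minimum description
    length) that scores possibly overlapping node covers. Includes model
    selection by MDL sweep and recursive bipartition, overlapping-cover
    quality metrics (overlapping NMI, extended modularity, enrichment),
    a planted-structure benchmark generator, readers for edge-list, GML
    and Pajek graphs, and JSON result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
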