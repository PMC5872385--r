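Package: percolor
Title: Perfect Colorings of Signed Regulatory Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sign-consistency analysis of signed, weighted influence graphs.
    Enumerates all up/down node colorings that lexicographically minimize
    (inconsistent targets, imperfect targets, imperfect-regulator weight),
    compresses the graph with three behavior-preserving topological
    reductions, extracts color-correlated components from the enumerated
    optima, scores components against discretized gene-expression profiles
    with a maximal-similarity statistic, and validates component scores by
    sign randomization with Welch's t-tests.  Includes generators for random
    signed graphs and synthetic discretized profiles, and metrics
    (specific-enrichment and clustering-quality indices over a term ontology)
    for comparing component decompositions with other clusterings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
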