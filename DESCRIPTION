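Package: senonet
Title: Senescence Gene Networks, Expression Permutation Nulls and Screen Scoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for seed-gene network analyses of cellular senescence:
    correlation-network construction with density-minimising threshold
    selection, seed plus first-order interaction subnetworks, topological
    candidate discovery (degree, betweenness, closeness, hypergeometric
    increased-connectivity p-values, edge-clustering module detection),
    directional gene-set overlap enrichment with Benjamini-Hochberg
    correction, a within-tissue expression-scrambling permutation null for
    multi-tissue differential-expression counts with an analytic
    Poisson-binomial oracle, Faith's phylogenetic diversity and its
    binomial-sampling expectation, and Z-score hit calling for siRNA
    high-content screens. Includes synthetic-data generators emulating the
    statistical structure of each input so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
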