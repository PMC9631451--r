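Package: etnet
Title: Quantitative Efficacy-Toxicity Network Scoring for Herb-Pair Compatibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative network-pharmacology analysis of a
    two-herb combination: rule-based ADMET screening of herb components,
    construction of bipartite component-target networks, estimation of
    initial component-on-target influence coefficients by a structured
    low-rank (Eckart-Young) matrix decomposition of target gene expression,
    enumeration of gene transmission chains from component targets to
    pathogenic genes over a protein-protein interaction network by a
    deterministic Dijkstra propagation, chain scoring with toxicity
    penalties and helper-herb bonuses, median-based chain retention,
    reverse screening of component pairs by a synergy score combining
    target overlap, toxicity counts and betweenness centrality, and
    coverage/over-representation assessment utilities. Includes a seeded
    synthetic-study generator with ground-truth factors for end-to-end
    validation, packaged worked-example fixtures, and a pipeline driver
    with file-based stage outputs and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
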