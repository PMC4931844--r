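Package: crnet
Title: Mutual-Information Network Analysis of Gene Expression Under Graded
    Calorie Restriction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers weighted gene networks from normalized expression
    matrices using Miller-Madow corrected mutual information followed by
    ARACNE data-processing-inequality pruning, and characterizes them:
    node strength, Barrat weighted clustering, hierarchy and scale-free
    diagnostics, eigenvector centrality and central-gene identification,
    modularity-based community detection, and cross-treatment comparison
    against Spearman-correlation networks. Includes an O-PLS-DA
    classifier with permutation validation and a synthetic expression
    generator with planted modules, hubs, graded rewiring across ordered
    treatment levels, and non-monotone gene-gene dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    mclust,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
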