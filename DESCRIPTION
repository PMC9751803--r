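Package: MicEcoNet
Title: Molecular Ecological Network Analysis of Microbial Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers signed co-occurrence networks from OTU abundance tables
    using a random matrix theory (RMT) based similarity threshold, computes
    global topological properties against degree-preserving random null
    ensembles, detects modules and classifies potential keystone taxa by
    within-module degree (Zi) and participation coefficient (Pi), and
    compares network stability between sample groups via robustness under
    random and keystone-targeted node removal. Includes a synthetic
    community generator with planted modules, hubs, and association signs
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
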