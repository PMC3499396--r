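Package: rmpmic
Title: Identify Effective siRNAs with Relative Mean Probabilities and Mini-Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores small interfering RNAs (siRNAs) by the relative mean
    probability of three position-specific Markov chain models (orders 1-3)
    trained on experimentally effective siRNAs, then separates effective
    from ineffective sequences with a nearest-pair mini-cluster
    agglomeration followed by single-linkage merging of unlabeled clusters
    into their nearest labeled neighbour, avoiding a hard two-class
    decision boundary. Includes an exact one-dimensional k-means baseline,
    sensitivity/precision evaluation, a resampling protocol for held-out
    assessment, and seeded generators for the simulation models used to
    benchmark the method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
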