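Package: coralnet
Title: Structure and Stability Analysis of Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community analysis of host-associated 16S OTU tables across
    hosts, sites and time points: median-of-ratios library-size
    normalization, prevalence-based core-microbiome detection, class-level
    abundance profiles, Bray-Curtis dissimilarity, sequential (Type-I)
    PERMANOVA for nested crossed designs with pairwise post-hoc tests and
    sequential Bonferroni (Holm) correction, permutation ANCOVA of
    distance decay in community dissimilarity, SIMPER dissimilarity
    decomposition, and a sample-correlation network pipeline (homophily
    and heterophily scores, leading-eigenvector community detection with a
    stratified Monte-Carlo modularity null, chi-squared module-factor
    association, classification rates, and eigenvector centrality).
    Includes a negative-binomial synthetic-data generator emulating a
    multi-species coral survey so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    igraph,
    vegan,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
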