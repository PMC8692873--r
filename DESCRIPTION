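Package: rhizonet
Title: Fungal Community Diversity, Guilds, and Co-Occurrence Networks in
    Root Endospheres and Rhizosphere Soil
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of amplicon-derived fungal OTU tables from
    paired root-endosphere and rhizosphere-soil samples: rarefaction, alpha
    diversity (Shannon, richness, Pielou evenness, Good's coverage) with
    nonparametric group tests, Bray-Curtis ordination (PCoA) and PERMANOVA,
    FUNGuild-style trophic-mode annotation with the single-guild rule,
    Spearman co-occurrence networks with greedy-modularity (CNM) module
    detection and Zi-Pi keystone classification, bipartite OTU-environment
    networks, and diversity-environment regression.  A synthetic-community
    generator with planted modules, hubs, connectors and a planted
    TOC-diversity association makes every stage testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
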