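Package: ncmtools
Title: Neutral Community Models and Phylogenetic Assembly Diagnostics for
    Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the balance of neutral (dispersal and drift) and
    deterministic (selective) processes shaping host-associated microbial
    communities from 16S OTU count tables. Fits the Sloan neutral community
    model by nonlinear least squares on beta-distributed occurrence
    frequencies, chains source-to-target comparisons through gut
    compartments or life-cycle stages, and partitions OTUs into neutral,
    over- and under-represented classes at a 95% Wilson confidence
    interval. Complements the model with net relatedness and nearest taxon
    indices (NRI/NTI) against a seeded taxon-shuffle null, generalized
    UniFrac distances with PERMANOVA and principal coordinates analysis,
    and alpha-diversity rank statistics with Benjamini-Hochberg control.
    Includes a Dirichlet-multinomial community simulator whose taxon-wise
    marginals are exactly the beta distribution the model fits, so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    biomformat,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
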