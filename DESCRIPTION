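Package: microterroir
Title: Spatial Heterogeneity and Diversity Analysis of Vineyard Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatially explicit analysis of grapevine-associated
    microbial communities from marker-gene (16S rRNA gene / ITS) amplicon
    surveys. Implements feature-table import and taxonomy-based filtering,
    bootstrapped rarefaction with median (alpha) and medoid (beta) summaries,
    k-mer decomposition of amplicon sequence variants, Jaccard and Bray-Curtis
    dissimilarities, principal coordinates analysis, Mantel distance-decay
    tests, one-way, pairwise and stratified (two-way) PERMANOVA with compact
    letter displays, gamma-diversity sample-accumulation curves, Gaussian
    process (kriging) spatial interpolation with Matern kernels, and a
    synthetic vineyard community generator with spatially autocorrelated
    taxa for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    geosphere,
    biomformat,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, Spatial, Software
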