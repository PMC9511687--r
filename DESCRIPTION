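Package: alpnet
Title: Transcriptome and Network Analysis of Autophagy, Lipid Metabolism
    and Proteostasis in Brewing Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for transcriptome and systems-biology
    analysis of lager-yeast beer fermentation. Performs pairwise differential
    expression between fermentation and propagation time points (moderated
    t-statistics via limma, or Welch t), intersects upregulated genes across a
    single-analysis and a meta-analysis into Pan-DEGs with meta-log2 fold
    changes, combines STRING/STITCH interaction channel scores with a
    prior-corrected noisy-OR, extracts the shortest-path subnetwork spanned by
    Pan-DEG seeds, classifies nodes into hub/bottleneck quadrants, detects
    walktrap communities, runs hypergeometric GO over-representation with
    Benjamini-Hochberg control plus Wang semantic similarity and k-means
    grouped enrichment heatmaps, and overlays transcriptome and proteome
    layers on a chemical-protein lipid-droplet network. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
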