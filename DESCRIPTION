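Package: spotsom
Title: Self-Organizing Map Portrayal of Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains a self-organizing map (SOM) on spot-level spatial
    transcriptomics data (10x-Visium-style input) and turns it into
    per-spot transcriptome "portraits": each gene's expression profile
    across spots is mapped onto a two-dimensional grid of metagenes,
    giving every spot a comparable grid-shaped image of its local
    expression landscape. On top of the trained map the package extracts
    modules of co-expressed genes by several segmentation modes, maps
    functional gene sets into the SOM and tests module enrichment,
    classifies receptor-ligand co-expression per spot, propagates
    expression-derived signals through signed directed pathway graphs,
    renders portrait and spatial images, and generates synthetic
    spot-by-gene fixtures with planted spatial domains for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
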