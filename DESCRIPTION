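Package: pneumotyper
Title: Low-Biomass Lung Microbiome Decontamination, Pneumotype
    Classification and Community Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for amplicon-based analysis of low-biomass lung
    microbiomes alongside high-biomass upper-respiratory-tract (URT)
    communities. Implements paired-read joining into V4 contigs,
    in-silico removal of reagent contamination by matching contigs
    against negative-control contigs (99 percent identity over at
    least 250 bp), direct reference-based genus assignment, group
    community statistics (representative log2 microbiomes,
    sample-to-profile correlations, a percent-overlap statistic,
    threshold abundance reports), iterative classification of lung
    samples into three pneumotypes (background, aspirate, unique), and
    alpha/beta diversity (Chao1 with rarefaction, inverse Simpson,
    Bray-Curtis, one-factor PERMANOVA). A Dirichlet-multinomial
    synthetic-community generator with read-level error and
    contaminant spiking emulates the statistical structure of such
    studies for validation and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
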