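Package: sweepscan
Title: Selective-Sweep Scans and Diversity Statistics for Phased Cattle-Style Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of selective sweeps from phased multi-population
    haplotype data: hard filtering of variant sites on quality annotations,
    nucleotide diversity, Weir-Cockerham FST, windowed linkage
    disequilibrium, identity-by-state distances, EHH decay curves and
    cross-population XP-EHH, a simplified XP-CLR composite-likelihood scan,
    an empirical-P genome-scan outlier pipeline with candidate-gene calling,
    breed-specific SNP enrichment tests (Fisher exact and Cochran-Armitage
    trend with Bonferroni correction), EIGENSTRAT-style PCA and IBS-based
    neighbor-joining trees.  Includes a founder-mosaic haplotype simulator
    with drift divergence and implantable sweeps so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
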