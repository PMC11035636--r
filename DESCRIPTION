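Package: lipidnet
Title: Molecular Networking and Information-Theoretic Analysis of Untargeted Lipidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for untargeted lipidomics of archaeal
    host-symbiont systems. Reads MS/MS spectra (Mascot Generic Format) and
    feature abundance tables, computes modified-cosine spectral similarity and
    builds feature-based molecular networks with mutual top-K edges and
    component-size capping, assigns archaeal ether lipid classes from
    diagnostic fragment ions, normalizes abundances (internal-standard
    recovery correction, protonated/ammoniated adduct merging, closure to
    relative abundance), calls presence/absence at a relative-abundance
    threshold and counts set intersections (UpSet), computes Shannon-entropy
    lipidome diversity and specialization indices, and runs multivariate
    statistics (Hellinger transform, PCA, Z-score hierarchical clustering,
    Tukey HSD with compact letter display). A synthetic-data generator plants
    known class shares, presence patterns, and specialization gradients so
    every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    ggplot2,
    patchwork,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
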