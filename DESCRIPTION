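Package: phenotax
Title: Numerical Taxonomy of Leaf Phenotypic Traits in Germplasm Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for phenetic (numerical-taxonomy) analysis of
    leaf macrostructure traits across germplasm collections such as the genus
    Malus. Provides ordinal trait codebooks and replicate-level observation
    tables; trait screening by Simpson diversity, Shannon-Wiener information
    and evenness indices for qualitative traits and by within- and
    among-germplasm coefficients of variation for quantitative traits;
    dimensionality reduction by correlation-matrix principal component
    analysis with eigenvalue and loading gates followed by Pearson
    correlation pruning; Ward.D2 hierarchical clustering of germplasms with
    k-cuts, subgroup summaries and Newick export; and pedigree-based
    ancestor-inclined distribution statistics (co-clustering probability,
    breeding frequency, section-by-cluster distributions, evolutionary-order
    correlation). A synthetic germplasm generator with known subgroup
    structure and tunable trait-inheritance fidelity supports validation of
    every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
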