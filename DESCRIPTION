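Package: strucnet
Title: Weighted Structural Brain Network Analysis with Permutation ANCOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Graph-theoretic analysis of weighted structural brain
    connectomes built from streamline-count connectivity matrices.
    Computes nodal (degree, strength, clustering, regional efficiency)
    and global (edge density, total strength, clustering coefficient,
    characteristic path length, small-worldness) network measures,
    compares them across diagnostic groups with permutation-based ANCOVA
    (Freedman-Lane residual permutation) and two-level Benjamini-Hochberg
    false-discovery-rate control, estimates covariate-adjusted group
    means, and maps network measures to cognitive test scores with
    partial correlations controlling for age, sex and education.  A
    synthetic-cohort generator with planted group effects and planted
    brain-behaviour correlations makes every pipeline stage testable
    without subject-level imaging data, and classical summary statistics
    (pooled t, one-way ANOVA F, Pearson chi-square) are recomputable
    exactly from published group means and standard deviations via
    moment-matched samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
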