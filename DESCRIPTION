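Package: floradisp
Title: Categorical Floral Morphospaces and Disparity Through Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying morphological disparity from categorical
    trait matrices with missing, inapplicable and polymorphic cells, as used
    in floral macroevolution. Implements the mean character difference (a
    Gower-type distance for mixed ordered/unordered categorical characters),
    per-group disparity metrics (mean and maximum pairwise distance,
    rarefaction, partial disparity, eccentricity), exact counting and
    constrained sampling of theoretical state combinations, nonmetric
    multidimensional scaling ordination with Shepard diagnostics, group
    statistics (Kruskal-Wallis with compact letter display, PERMANOVA with
    Bonferroni pairwise tests, Pearson correlations), and Mk-model ancestral
    state reconstruction (ER/ARD maximum likelihood with AIC selection and
    stochastic node sampling) whose most probable ancestral combinations can
    be placed into the morphospace. A synthetic-data generator reproduces the
    statistical structure of such datasets so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ape,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
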