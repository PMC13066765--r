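Package: betascape
Title: Landscape-Scale Drivers of Tree Beta Diversity and Endemism
Version: 0.1.0
Authors@R:
    person("betascape", "developers", email = "betascape@example.org",
           role = c("aut", "cre"))
Description: Tools for landscape-scale analysis of how habitat amount,
    habitat fragmentation, spatial distance and regional climate shape
    abundance-based beta diversity and community endemism of tree
    communities. Provides a synthetic-study generator (neutral habitat
    landscapes, species pools with endemism categories, distance-decay
    communities), hexagonal landscape tessellation with inventory filters,
    FRAGSTATS-style fragmentation metrics on binary habitat rasters,
    the abundance-based multi-site Bray-Curtis partition and a modified
    abundance-based Raup-Crick null model, community-weighted mean
    endemism scoring, and beta/Gaussian regression with all-subsets AIC
    model selection plus collinearity (VIF) and spatial autocorrelation
    (Moran's I) diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
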