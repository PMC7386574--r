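Package: grassim
Title: Individual-Based Simulation and Inverse Parameterization of
    Temperate Grassland Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual- and process-based simulator of mown temperate
    grassland communities in the gap-model tradition. Plants on a 1 m x 1 m
    patch grow from a daily carbon balance (Beer-Lambert canopy shading,
    saturating leaf light response, maintenance and growth respiration),
    compete for light, space, soil water and mineral nitrogen, recruit from
    external seed rain, senesce, and die from intrinsic, starvation and
    crowding (self-thinning) mortality; plots are mown to a fixed height on a
    schedule. The package also provides the multi-constrained inverse
    parameterization used to fit species traits to observed vegetation
    patterns (MAPE and nrmse costs over annual time series of aboveground
    biomass, leaf area index, vegetation height and cover, of monocultures,
    mixtures and relative yields) with dynamically dimensioned search,
    differential evolution and simulated annealing optimizers, a synthetic
    temperate climate generator, and a replicate-averaged evaluation layer
    (ordinary least squares regression, normalized RMSE, normalization by
    pattern maxima, relative yields of mixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
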