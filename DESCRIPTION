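Package: cpdd
Title: Species Coexistence Under Positive Density-Dependent Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how conspecific positive density dependence
    acting on mortality (an Allee-type effect in which extrinsic mortality
    declines with population density) shapes coexistence in Lotka-Volterra
    competition models. Provides two-species models with three forms of
    species asymmetry (asymmetric resource competition, differences in basal
    mortality, asymmetric reproductive interference), an N-species
    generalization, equilibrium location with feasibility and local-stability
    analysis, invasion growth rates, classification of coexistence equilibria
    as local or global attractors, parameter-plane coexistence scans, seeded
    random community generation, and deterministic multispecies richness and
    sequential-assembly simulations with extinction thresholding. Numerical
    integration uses an adaptive Dormand-Prince Runge-Kutta scheme
    implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
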