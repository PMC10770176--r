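Package: hapflow
Title: Micro-Pharmacology Simulation of Hypoxia-Activated Pro-Drug Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit micro-pharmacokinetics/pharmacodynamics
    simulator of hypoxia-activated pro-drug (HAP) treatment in a digitized
    two-dimensional tumor tissue. Interstitial fluid flow past immobile tumor
    cells is computed with the method of regularized Stokeslets; oxygen,
    inactive pro-drug, active drug and a metabolic sensitizer are advanced by
    explicit reaction-advection-diffusion steps on a cell-masked grid; cells
    accumulate active drug through boundary pseudo-receptors and die past a
    lethal threshold. Treatment schedules combining the pro-drug with a
    vasodilator and a metabolic sensitizer can be swept over injection offsets
    to locate schedules that maximize tumor cell kill.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
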