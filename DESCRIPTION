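Package: fructoflux
Title: Positional 13C-Isotopomer Simulation and Flux Inference for the
    Yeast Glucose-to-Fructose Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and flux inference for resting-cell
    [1-13C]/[2-13C]glucose tracer experiments in fructophilic yeasts that
    dephosphorylate fructose-6-phosphate to free fructose. Provides
    atom-to-atom carbon transition maps for glycolysis, the reversible
    aldolase/triose-phosphate-isomerase step and a lumped pentose phosphate
    cycle; an exact positional-isotopomer algebra; a quasi-steady-state
    simulator of extracellular label time courses; a synthetic NMR
    time-course generator with a noise and detection-limit model; and
    estimators of glucose uptake, fructose excretion, triose-to-hexose
    back-flux and pentose-phosphate-pathway entry flux with bootstrap
    standard deviations, returned as a classed model object.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
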