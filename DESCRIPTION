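Package: pallidopath
Title: Pathway Activation Modelling for Pallidal Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale biophysical model of internal globus pallidus (GPi)
    deep brain stimulation. Generates a synthetic pallidal scene (ellipsoidal
    nuclei, DBS lead, tissue conductivities), populates pallidofugal,
    pallidosubthalamic, striatofugal and internal-capsule axon pathways,
    computes the extracellular potential of a stimulation setting with an
    analytic volume-conductor surrogate, simulates MRG-type double-cable
    myelinated axons to find activation thresholds by binary search, and
    summarizes percent pathway activation. Companion modules generate
    synthetic robotic-manipulandum rigidity trials, compute stiffness and
    angular-impulse measures, and link pathway activation counts to rigidity
    change through linear mixed-effects models with exact paired
    signed-rank and Kendall rank statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
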