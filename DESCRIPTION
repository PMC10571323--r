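Package: monodomain
Title: Finite-Element Monodomain Simulation of Cardiac Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Serial finite-element solver for the cardiac monodomain
    reaction-diffusion equation with pluggable ionic models
    (Aliev-Panfilov, Bueno-Orovio, ten Tusscher-Panfilov 2006,
    Courtemanche-Ramirez-Nattel), heterogeneous labelled subdomains,
    fiber-based anisotropic conduction, configurable stimulation
    protocols, implicit-explicit backward-differentiation time
    integration with ionic current interpolation, activation mapping,
    checkpointing, and the N-version slab benchmark as its verification
    surface. Meshes are built in-package (structured hexahedral slabs)
    or imported from gmsh MSH and VTU files; results are written as VTU
    time series and CSV traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
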