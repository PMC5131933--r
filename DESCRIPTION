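Package: spiralps
Title: Phase-Singularity Detection and Comparison for Cardiac Spiral-Wave Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for locating phase singularities (spiral-wave cores, rotors)
    in two-dimensional transmembrane-voltage movies of cardiac fibrillation.
    Implements the classical Iyer-Gray line-integral detector and a fast
    location-centric detector based on the temporal phase discontinuity at the
    singular site, together with time-delay phase embedding, a Hausdorff-distance
    framework for comparing detected point sets, parameter sweeps, and runtime
    benchmarks. Test inputs are generated internally: a monodomain
    reaction-diffusion solver with the Courtemanche-Ramirez-Nattel human atrial
    cell model (control and ionic-remodeling scenarios, cross-field S1-S2
    initiation), a fast two-variable excitable-medium surrogate, and analytic
    spiral movies with exactly known core locations.
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
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
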