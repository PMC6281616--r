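Package: cgtubes
Title: Coarse-Grained Membrane Nanotube Simulation and Fluorescence Tube
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates membrane nanotubes with a solvent-free three-site
    coarse-grained lipid model and frozen protein ring scaffolds, and
    quantifies scaffold-driven remodeling: tube bulging, compensatory
    thinning and spontaneous fission. Includes builders for bilayer tubes
    and ring scaffolds, NVT dynamics with a Nose-Hoover chain thermostat,
    trajectory observables (lumen-radius profiles, thinning time series,
    scission detection, interleaflet mixing), a fluorescence morphometry
    pipeline (intensity-to-radius calibration, bulge and fission
    kinetics, FRAP mobile-fraction fitting, scaffold growth rates), and
    synthetic-image generators that provide ground truth for every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
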