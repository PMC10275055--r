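Package: fccs
Title: Simulation and Analysis of Fluorescence Cross-Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying protein-protein interactions in live cells by
    fluorescence cross-correlation spectroscopy (FCCS). Simulates two-channel
    photon count traces from Brownian dynamics in a 3D Gaussian confocal
    observation volume (including triplet blinking and a slow chromatin-bound
    component), computes auto- and cross-correlation curves with direct and
    multi-tau correlators, fits two-component diffusion models with a triplet
    term, calibrates the observation volume from reference-dye measurements,
    and derives dimerization statistics: relative cross-correlation amplitude
    (RCA), molecular brightness (counts per second per molecule, CPM), the
    diffusion coefficient and fraction of the DNA-bound component, dose-response
    (IC50/Hill) fits, and Cheng-Prusoff potency shifts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
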