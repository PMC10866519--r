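Package: gastruloidCPM
Title: Cellular Potts Simulation and Shape Analysis of Elongating Gastruloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-dimensional Cellular Potts (Glazier-Graner-Hogeweg) simulator of
    gastruloid elongation with an edge-list Monte Carlo sampler, a filopodial-tension
    convergent-extension term with self-organized polarization, and differential-adhesion
    model variants, together with the matching analysis toolkit: LOCO-EFA lobe-contribution
    shape spectra, a Fasano-Franceschini two-dimensional Kolmogorov-Smirnov test,
    watershed-based segmentation of wide-field microscopy images, trajectory
    rotation/drift correction with axis projections, and synthetic-data generators
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    stats,
    grDevices,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
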