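Package: sasbead
Title: Monte Carlo Bead Models and Virtual Small-Angle Scattering Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds particles from geometrical subunits (spheres, cylinders,
    ellipsoids, hollow bodies and more) as uniform-density point clouds with
    per-subunit excess scattering-length densities, and computes their
    small-angle scattering via the Debye formula accelerated by a binned
    pair-distance histogram. Supports Gaussian size polydispersity,
    hard-sphere and fractal-aggregate structure factors with the decoupling
    approximation, interface-roughness smearing, and a virtual experiment
    that scales the forward scattering with concentration and particle
    volume and adds realistic synchrotron-like noise. Includes analytic
    form factors (sphere, cylinder, ellipsoid of revolution, core-shell
    cylinder) and a weighted least-squares fitter for validating models
    against simulated data.
License: GPL (>= 3)
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
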