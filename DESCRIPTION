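Package: granulediff
Title: Solute Diffusion Analysis for Granular Sludge Biofilms
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and estimation machinery for transient-uptake
    diffusion experiments on spherical granular biofilms. Implements the
    finite-bath (limited-volume) analytical solution for diffusion of a
    non-reactive solute into a population of identical spheres, transcendental
    eigenvalue root-finding, multi-start nonlinear least-squares estimation of
    the effective diffusion coefficient with Monte-Carlo uncertainty
    propagation, temperature conversion of diffusivities via the water
    viscosity ratio, log-log diffusivity versus molecular-weight scaling with
    regression comparison t-tests, granule-core penetration assessment, and
    bookkeeping for serial-ultrafiltration COD size fractionation of influent
    wastewater. Includes a synthetic-data generator and an independent
    finite-volume PDE oracle so the whole pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
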