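Package: saxpcs
Title: Small-Angle X-Ray Photon Correlation Spectroscopy of Dilute
    Brownian Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of small-angle X-ray photon correlation spectroscopy
    (XPCS) and small-angle X-ray scattering (SAXS) measurements of dilute
    nanoparticle suspensions such as virus particles. Provides detector
    geometry and momentum-transfer (Q) maps, a multi-tau photon correlator
    with symmetric normalisation and pixel binning performed before
    division, polydisperse-sphere form-factor fitting for the geometric
    radius, single-exponential and Stokes-Einstein fits for the
    hydrodynamic radius, a subset-stability diagnostic, and a synthetic
    Brownian speckle generator so the full pipeline can be validated
    end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
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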