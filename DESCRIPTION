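Package: micellr
Title: Micelle Structure and Interactions from Small-Angle Scattering,
    Surface Tension and Conductivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of charged micelles as model colloids. Fits absolute-
    intensity small-angle X-ray scattering (SAXS) curves with a polydisperse
    core-shell sphere form factor combined with the Hayter-Penfold rescaled
    mean spherical approximation (RMSA) structure factor for screened-Coulomb
    (Yukawa) interactions, and derives electrostatic quantities from the fit:
    Debye screening length, surface (zeta) potential, effective charge and
    inter-micellar potential-energy curves. Computes micelle molar mass and
    association number from absolute forward scattering, and determines the
    critical micelle concentration, surface excess and area per molecule from
    surface-tension and conductivity series via two-segment breakpoint fits.
    Includes ground-truth synthetic-data generators for every pipeline stage
    and a numerical Ornstein-Zernike reference solver used to validate the
    analytic structure factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
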