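Package: ntcpsim
Title: Monte Carlo Assessment of Contouring Differences in NTCP Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate how discrepancies between two contour sets of
    the same organ at risk translate into performance differences between the
    normal tissue complication probability (NTCP) models derived from them.
    Implements the logistic NTCP model with normalized slope parameterization,
    maximum-likelihood fitting of (D50, gamma), Bernoulli outcome simulation,
    paired bootstrap AUC comparison, a Monte Carlo engine sweeping slope,
    dosimetric parameter and cohort size, a Gaussian-copula synthetic cohort
    generator, and geometric/dosimetric contour metrics (Dice, surface Dice at
    tolerance, mean dose, VxGy) computed from voxel masks and aligned dose
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
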