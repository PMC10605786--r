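Package: cerebromech
Title: Cerebral Artery Wall Mechanics, Fiber Microstructure, and
    Birefringence Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying structural and mechanical
    remodeling of cerebral artery walls. Converts biaxial
    extension-inflation myograph recordings into mid-wall stretches and
    Cauchy stresses under thin-wall incompressible kinematics, fits
    exponential stress-stretch laws and derives tangent stiffness,
    quantifies fiber-depleted ("empty band") regions at the
    media-adventitia interface from binarized multiphoton projections via
    a 30x30 grid area-fraction statistic, inverts six-frame
    polarizer-stepped image stacks into relative-retardance and
    optic-axis orientation maps, and runs the accompanying composition
    and group-comparison statistics (normality-gated two-group tests,
    Welch differential abundance with Benjamini-Hochberg control,
    collagen composition with Bonferroni correction). Includes seeded
    synthetic-data generators with known ground truth for every input
    modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
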