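Package: ribbonmetrics
Title: Density-Profile Morphometry of Bacterial Cellulose Ribbons in
    Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Peak-to-peak metrology for cryo-electron tomograms of
    cellulose-producing bacteria: averaged, normalized 1-D density
    profiles along annotated lines, sub-voxel peak detection, FWHM
    width estimation, and assembly of the profile measurements into
    named envelope/ribbon/cortical-belt quantities with tight/loose
    classification. Includes a synthetic tomographic phantom generator
    with a cryo-ET imaging model (Gaussian defocus-blur proxy,
    missing-wedge Fourier mask, additive noise) and ground-truth
    sidecars for parameter-recovery validation, FIB-lamella biofilm
    census geometry, an exact small-sample Mann-Whitney / Wilcoxon
    testing protocol, and MRC2014 volume input/output.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
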