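Package: thermoscreen
Title: Inverse Thermal Modeling for Breast Cancer Screening from Infrared
    Surface Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state Pennes bioheat simulation of voxelized breast
    phantoms with a size-dependent tumor heat source, multi-view infrared
    surface-temperature rendering with a camera noise model, and
    Levenberg-Marquardt inverse estimation of tumor presence, size, and
    location from surface temperatures. Includes synthetic phantom
    generation, a transcribed clinical cohort fixture, and a validation
    pipeline reporting size and location errors, sensitivity, and
    specificity on phantom batches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
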