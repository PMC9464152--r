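Package: imatq
Title: Quantification of Intermuscular Adipose Tissue and Muscle Fat
    Fraction from Dixon MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify myosteatosis from Dixon fat-fraction magnetic
    resonance images. Separates intermuscular adipose tissue (IMAT) from
    muscle tissue inside a fascial or muscle region of interest using a
    patient-specific bimodal-histogram local-minimum threshold, computes
    compartment volumes, fat fractions and body-composition normalizations,
    and fits linear and quadratic age trends with annual percent change,
    standard error of the estimate and percent coefficient of variation.
    Includes a synthetic phantom and cohort generator with voxel-level
    ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
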