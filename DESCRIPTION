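Package: specfinger
Title: Mid-Infrared Metabolic Fingerprinting with OSC-PLS-DA and Gaussian Band Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating clinically similar chronic pain conditions
    (fibromyalgia and Long COVID) from attenuated-total-reflectance mid-infrared
    spectra of the low-molecular-weight blood fraction. Implements the full
    chemometric chain: Savitzky-Golay smoothing and second-derivative
    pretreatment, orthogonal signal correction, NIPALS partial least squares
    discriminant analysis with leave-one-out cross-validation, external
    validation and ROC analysis, and second-derivative-guided Gaussian multipeak
    deconvolution of the 1500-1700 cm-1 amide/carboxylate region with relative
    band-area statistics (one-way ANOVA and Tukey HSD with compact letter
    display). A synthetic-spectrum generator with known class band structure
    stands in for patient data so every stage is testable end to end.
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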