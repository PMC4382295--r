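Package: elastifit
Title: Hyperelastic Characterization of Soft-Tissue Uniaxial Tension Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for high-rate uniaxial tension tests on soft
    biological tissue cylinders glued between platens. Converts raw
    displacement/force records into Lagrange (nominal) stress versus
    corrected stretch curves using the glued-cylinder stretch correction,
    fits four hyperelastic model families (Fung, Gent, one-term Ogden, and
    a three-parameter exponential stress law) by multi-start nonlinear
    least squares, and summarizes rate-dependent behaviour (end stress,
    coefficient of variation across replicates, secant moduli, pairwise
    Welch tests). A calibrated synthetic-data generator emulates the study
    design (3 strain rates x 6 replicates to 30% grip strain) so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
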