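Package: protpamm
Title: Competing-Risks Piece-Wise Exponential Additive Models for ICU
    Protein Intake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models time-varying associations between daily protein intake
    and competing hospital outcomes (in-hospital death, live discharge) of
    critically ill patients using piece-wise exponential additive mixed
    models fitted as penalized Poisson regressions. Provides quantification
    and categorization of daily enteral/parenteral protein intake,
    transformation of patient records into piece-wise exponential data with
    lag/lead cumulative-effect windows, a penalized spline hazard fitter
    with ICU random intercepts and REML smoothing selection, hypothetical
    diet hazard-ratio contrasts with confidence bands, cause-specific
    cumulative incidence functions, and a synthetic cohort generator with
    known ground-truth hazard surfaces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
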