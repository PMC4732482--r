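Package: troutherm
Title: Thermal Physiology and Metabolic Scope Analysis for Lake Trout
    Acclimation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reducing intermittent-flow respirometry oxygen
    traces to routine and maximal metabolic rate, metabolic scope and
    post-exercise recovery rate; for converting critical thermal maximum
    (CTmax) ramping trials into per-fish upper thermal tolerance values;
    and for the mass-adjusted factorial inference layer (two-factor
    ANOVA/ANCOVA with a body-mass covariate, adjusted least-squares
    means at a reference mass, allometric mass exponents, homogeneity of
    regression slopes, and Tukey HSD comparisons) used in common-garden
    thermal acclimation studies. Includes a calibrated synthetic-data
    generator emulating a four-population by four-acclimation-temperature
    design so the full pipeline can be exercised and validated without
    access to raw laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
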