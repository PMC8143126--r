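Package: bovitherm
Title: Hide-Color Albedo and Surface-Temperature Modeling for Range Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the thermal ecology of differently colored range
    cattle in cold environments: snow-referenced albedo estimation from
    8-bit digital images with ground-truth scene simulation, per-color
    albedo comparison (arcsine transform, Kruskal-Wallis, Cohen's d),
    construction and staged AICc model selection of animal
    surface-minus-ambient temperature differences with Akaike weights and
    confidence-interval screening, per-color slope regression with ANCOVA
    heterogeneity tests, and radiative and convective heat-transfer
    calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    png,
    jsonlite,
    yaml,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
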