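Package: maniclo
Title: Thermal Manikin Data Reduction for Clothing Insulation and
    Evaporative Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces zone-level thermal manikin measurements to whole-body
    clothing thermal insulation (global, serial and parallel aggregation
    methods) and, in sweating (wet) mode, to total and clothing evaporative
    resistance with skin-temperature correction and moisture permeability
    indices. Ships a machine-readable wardrobe database of Dutch firefighter
    clothing items and ensembles, item-to-ensemble insulation summation and
    clothing-area-factor regression models with refitting tools, a
    steady-state detector and repeatability checks for trial quality
    control, and a forward simulator of dry and wet manikin trials with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
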