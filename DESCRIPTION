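Package: treelim
Title: Resource-Limited Maximum Tree Height from Allometric Scaling and
    Canopy Energy Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A steady-state model of the tallest tree a climate can
    sustain. Allometric power laws tie trunk diameter, canopy and root
    geometry, leaf number, and the basal metabolic water requirement to
    overall tree height; a canopy energy budget converts long-term-mean
    meteorology (solar radiation, air temperature, humidity, wind,
    pressure) into an evaporative flow rate; and precipitation captured
    over the root footprint caps the available supply. Maximum
    sustainable height is the largest size at which the required,
    evaporative, and available flows remain ordered. The package also
    derives height-dependent canopy albedo, environment-optimal stomatal
    density and leaf size, temperature-shift sensitivity of predicted
    heights, and scaling-exponent sensitivity, and ships a synthetic
    site-climatology generator so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
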