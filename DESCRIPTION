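Package: budforce
Title: Thermal-Time Estimation and Bud-Break Simulation for Dormant Fruit Buds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the apparent base temperature and growing-degree-hour
    (GDH) thermal-time requirement for floral bud break from constant-temperature
    forcing experiments, using the x-intercept of the linear regression of
    development rate (1/hours to 0.5 bud-break fraction) on forcing temperature.
    Includes a weather-driven phenology simulator that accumulates chill hours
    (hours below 7.2 degrees C) from the start of the dormant season and then
    GDH above a trait-specific base temperature, to compare predicted bud-break
    timing of alternative heat-requirement trait combinations against a
    reference. Seeded synthetic generators for forcing time courses and hourly
    winter weather make both halves testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
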