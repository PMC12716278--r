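Package: chillmap
Title: Chill-Injury Accumulation Models and Overwintering Habitat
    Suitability Mapping for Insect Biological Control Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits logistic time-temperature survival models to cold-exposure
    assay data to estimate the upper limit of the chill injury zone (ULCIZ)
    and the sum of injurious temperatures (SIT), accumulates chill-injury
    mortality over fluctuating temperature records via a logit-additive
    recursion, organizes weather-station series into quality-controlled
    winter years, interpolates station mortalities onto a lat/lon lattice by
    ordinary kriging with a spherical semivariogram, classifies habitat
    suitability, thins occurrence records, and relates predicted winter
    mortality to field collection counts. Includes seeded synthetic-data
    generators for every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
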