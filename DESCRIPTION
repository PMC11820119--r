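Package: gwpstar
Title: Build GWP* Food Composition Databases and Dietary Climate Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assigning GWP* climate-footprint values (kg CO2e per kg
    of food) to every item of a hierarchical food composition database and for
    applying the resulting database to dietary intake records. Supports direct
    and approximate matching against a published reference table, recursive
    recipe decomposition by weight-proportional summation with an exclusion
    rule for unmatched ingredients, food-group averaging, and fruit/vegetable
    processing conversion factors, all with per-food stage/step provenance and
    coverage diagnostics. A seeded synthetic-data generator produces complete,
    internally consistent input bundles with known ground truth so the whole
    pipeline can be exercised without access to restricted source data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
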