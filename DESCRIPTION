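Package: ducktrack
Title: Year-Round Light-Level Geolocation for Arctic Sea Ducks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archival light-level geolocator (GLS) records
    from sea ducks across a full annual cycle. Converts raw light series into
    validated sunrise/sunset events (including equinox and polar-day handling),
    estimates positions by the threshold method with known-site, fixed-angle and
    Hill-Ekstrom sun-elevation calibrations, and fits a particle-based
    probabilistic track model that combines twilight geometry with movement,
    sea-surface temperature, land/ice masks and a conductivity-derived
    water-type likelihood that separates freshwater, brackish and marine
    habitats. Includes rule-based segmentation of the annual cycle into six
    staging periods with stopover detection and phenology summaries, kernel
    utilization distributions with mass-quantile contours, and a synthetic-bird
    generator (scripted itineraries, forward-modelled light, conductivity,
    wet/dry and temperature sensors over an abstract world) so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
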