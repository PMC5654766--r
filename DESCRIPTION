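Package: fledgetrack
Title: Movement Analysis for Central-Place Foraging Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for GPS tracks of central-place foraging
    seabirds. Cleans and regularises fix tables, splits tracks into foraging
    trips, labels each location with one of four behavioural states (resting,
    intensive foraging, travelling, relocating) from speed and turning angle,
    detects and merges area-restricted search (ARS) zones, estimates kernel
    utilisation areas, detects dyadic at-sea associations with a degree/time
    proximity rule, and tests whether associations co-occur with ARS behaviour
    more often than expected under independence. Includes a seeded
    correlated-random-walk colony simulator with known ground-truth behaviour
    states and planted co-movement episodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
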