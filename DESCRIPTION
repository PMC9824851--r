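Package: padelquery
Title: A Query Language for Video-Based Tracking Data of Padel Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for exploratory analysis of per-frame player-tracking data
    from padel matches. Builds a navigable hierarchy of temporal play units
    (match, set, game, point, shot, frame) from three tabular inputs (points,
    shots and per-frame player positions), reconstructs the tennis-style score
    progression, derives player kinematics (speed, acceleration, distances to
    the net and walls, shot direction angles), and exposes a compact
    predicate-based query language whose results are tibbles with per-row
    video deep links. Ships a multi-alias shot-type taxonomy, an extensible
    tag system, a catalog of ready-made tactical queries, and a seeded
    generator of synthetic match bundles for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
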