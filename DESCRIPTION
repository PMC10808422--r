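Package: faclink
Title: Triangulation of Multi-Source Health Facility Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidates many overlapping, noisy health-facility lists into a
    single list of unique, geolocated facilities. Implements name
    standardization for French-orthography facility names, Jaro-Winkler fuzzy
    matching with regional blocking, transitive-closure clustering of accepted
    matches, Haversine-based geospatial conflict detection, hierarchical
    source-preference GPS assignment, and coverage/discordance reporting.
    Ships a seeded synthetic multi-source registry generator with ground
    truth, so entity-resolution quality (pairwise precision, recall, F1) is
    measurable end-to-end without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    stringi,
    readr,
    ggplot2,
    igraph,
    generics,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
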