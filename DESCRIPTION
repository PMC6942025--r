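Package: nichesvm
Title: Presence-Only Niche Modelling with Native-Species Contrast Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species distribution modelling for recently invaded regions where
    absence data are unreliable. Occurrence records of an invasive mosquito are
    separated from pooled occurrence records of co-occurring native species in
    climate space using a radial-basis-function support vector machine with
    sigmoid (Platt) probability calibration, optional genetic-algorithm
    covariate selection with the weighted f1 score as fitness, temporal
    hold-out validation, and application of the calibrated model across
    gridded climate layers to produce occurrence-probability maps. A
    synthetic-world module simulates multi-year climate grids and virtual
    species with configurable Gaussian niche responses so the full pipeline
    can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    kernlab,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
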