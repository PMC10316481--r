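Package: nicheshift
Title: Environmental Niche Shifts and Invasion Risk for Introduced Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies environmental niche shifts between the reference
    (international) and introduced (e.g. Australian) ranges of invasive
    species, and maps invasion risk. Implements PCA-calibrated environmental
    space with kernel-smoothed occurrence densities, Schoener's D overlap,
    niche expansion/stability/unfilled indices and randomization similarity
    tests; presence-background maximum-entropy habitat suitability with
    target-group backgrounds, cross-validated AUC, permutation-importance
    variable selection and fixed-cumulative thresholding; multivariate
    environmental similarity surfaces (MESS); accumulated-cost invasion-risk
    surfaces; and alpha-hull range area accounting. A virtual-species
    simulator generates landscapes with known niche truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
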