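Package: dropphage
Title: Droplet-Based Detection, Enumeration and Isolation Analysis for
    Bacteriophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for water-in-oil droplet assays in which
    bacteriophages are co-encapsulated with host cells, propagated, stained
    with an intercalating dye and read out by droplet cytometry. Provides a
    synthetic event-table generator (Poisson co-encapsulation, burst-cycle
    propagation, multiplicative signal noise and a starvation artifact
    channel), forward-scatter size filtering and fluorescence threshold
    gating, Poisson occupancy statistics with two estimators of the mean
    phage load per droplet, plaque-assay titer arithmetic, and 96-well
    spot-assay digitization with binomial recovery statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
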