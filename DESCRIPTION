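Package: seascapeDD
Title: Spatio-Temporal Density-Dependence Indices for Gridded Fish Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the spatial indices used to diagnose density-dependence in
    body condition of pelagic fish populations surveyed on a regular grid of ICES
    statistical rectangles: Fulton's condition factor from individual length-weight
    records, above-median centres of gravity with leave-one-out confidence
    intervals, centre-of-gravity separation trajectories, per-year spatial
    density-condition rank correlations, and distance-weighted Moran's I as a
    patchiness index, with autocorrelation-adjusted significance tests for the
    resulting time series. Includes a synthetic seascape generator emulating a
    Baltic-Proper-like survey so the full pipeline is testable without access to
    restricted survey databases.
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
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
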