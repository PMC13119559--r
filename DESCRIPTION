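Package: lcintensity
Title: Stratified Intensity Analysis of Land-Cover Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Intensity Analysis of multi-temporal categorical
    land-cover maps at the interval, category and transition levels, extended
    with a stratified (regional) decomposition of every statistic. Takes
    co-registered categorical rasters or pre-computed area cross-tabulation
    matrices, classifies intervals as fast or slow, categories as active or
    dormant, and transitions as targeted or avoided against uniform-intensity
    baselines; decomposes continental change budgets into per-stratum
    contribution percentages; summarises cross-interval stationarity, dominant
    transition pathways, first-to-last trajectory maps and targeted-transition
    networks. Includes a stratified Markov-chain landscape simulator with exact
    expected transition matrices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
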