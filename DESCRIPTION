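Package: hfaccess
Title: Comparing Modelled and Perceived Accessibility to Health Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare modelled spatial accessibility to health
    facilities with survey-derived perceived accessibility. Computes four
    accessibility surfaces on raster grids (Euclidean distance to the nearest
    facility, motorized and walking cost-distance over friction surfaces, and
    a truncated Gaussian kernel density of facilities), builds a
    perceived-accessibility index from cluster-level survey counts, and
    evaluates their agreement with stratified Spearman rank correlations. A
    geomasking simulator reproduces the DHS cluster-displacement scheme and
    quantifies its effect on correlations by Monte-Carlo replication, and
    population-by-accessibility-class summaries aggregate gridded population
    counts into distance or travel-time bands. A synthetic-data generator
    produces landscapes, facilities, population grids and survey clusters
    with known ground truth so the full study runs end-to-end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
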