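#!/usr/bin/env Rscript
# Stage 1 — simulate the study region.
#
# Generates the synthetic landscape (walking/motorized friction with roads
# and impassable barriers, population blobs), 80 population-weighted health
# facilities, a 4x3 admin tiling and 600 survey clusters whose yes/no
# answers follow a logistic link on true Euclidean distance to the nearest
# facility. Everything is written as plain-text GIS files so later stages
# (and anyone else) can start from disk.

library(hfaccess)

seed <- 1
bundle_dir <- "scratch/study_bundle"
dir.create("results", showWarnings = FALSE)

b <- make_study_bundle(bundle_dir, seed = seed)

cat("Landscape:", b$landscape$population$nrows, "x",
    b$landscape$population$ncols, "km cells; ",
    sum(is.infinite(b$landscape$walk$grid$values)), "barrier cells\n")
cat("Facilities:", nrow(b$facilities), " Clusters:", nrow(b$clusters), "\n")
cat("Mean perceived access:",
    round(100 * mean(perceived_access(b$clusters)), 1), "%\n")
cat("Bundle written to", bundle_dir, "\n")
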