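#!/usr/bin/env Rscript
# Stage 2 — compute the four modelled-accessibility surfaces.
#
# Reads the stage-1 bundle from disk and computes: ED (meters to nearest
# facility), CD-M and CD-W (accumulated travel time in minutes over the
# motorized/walking friction grids), and KD (Gaussian kernel density of
# facilities, 15 km truncation). Surfaces are written as ESRI ASCII rasters.

library(hfaccess)

bundle_dir <- "scratch/study_bundle"
out_dir <- "scratch/surfaces"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pop <- read_raster(file.path(bundle_dir, "population.asc"))
walk <- friction_surface(read_raster(file.path(bundle_dir, "friction_walk.asc")),
                         "walking")
motor <- friction_surface(read_raster(file.path(bundle_dir, "friction_motor.asc")),
                          "motorized")
fac <- read_facilities_csv(file.path(bundle_dir, "facilities.csv"))

surfaces <- list(
  ED = euclidean_surface(pop, fac),
  CD_M = cost_distance_surface(motor, fac),
  CD_W = cost_distance_surface(walk, fac),
  KD = kernel_density_surface(pop, fac))

for (m in names(surfaces)) {
  write_raster(surfaces[[m]]$grid,
               file.path(out_dir, paste0(tolower(m), ".asc")))
  v <- surfaces[[m]]$grid$values
  cat(sprintf("%-5s %-13s range [%.3g, %.3g], %d unreachable cells\n",
              m, paste0("(", surfaces[[m]]$units, ")"),
              min(v[is.finite(v)]), max(v[is.finite(v)]),
              sum(is.infinite(v))))
}
cat("Surfaces written to", out_dir, "\n")
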