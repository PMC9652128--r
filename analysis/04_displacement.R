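#!/usr/bin/env Rscript
# Stage 4 — displacement robustness.
#
# Re-applies the DHS-style geomasking displacement to the cluster points 30
# times (urban <= 2 km, rural <= 5 km, 1% of rural <= 10 km), re-extracts
# the four surfaces and recomputes the PA-MA Spearman correlations each
# time. Reports the spread of replicate correlations and the share of
# replicates in which displacement lowered |r_s|.

library(hfaccess)

bundle_dir <- "scratch/study_bundle"
surf_dir <- "scratch/surfaces"
dir.create("results", showWarnings = FALSE)

clusters <- read.csv(file.path(bundle_dir, "clusters.csv"))
surfaces <- lapply(c(ED = "ed", CD_M = "cd_m", CD_W = "cd_w", KD = "kd"),
                   function(m) {
                     units <- c(ed = "meters", cd_m = "minutes",
                                cd_w = "minutes", kd = "dimensionless")[[m]]
                     access_surface(read_raster(file.path(surf_dir,
                                                          paste0(m, ".asc"))),
                                    toupper(m), units)
                   })

res <- replicate_displacement_study(clusters, surfaces, R = 30, seed = 5)
write.csv(res$replicates, "results/displacement_replicates.csv",
          row.names = FALSE)
write.csv(res$summary, "results/displacement_summary.csv", row.names = FALSE)

cat("Displacement effect on PA-MA |r_s| (30 replicates):\n")
print(res$summary[, c("method", "baseline_rho_abs", "mean_rho_abs",
                      "min_rho_abs", "max_rho_abs", "share_attenuated")],
      digits = 3)
cat(sprintf("\nOverall, %.1f%% of displacements lowered |r_s|.\n",
            100 * mean(res$summary$share_attenuated)))
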