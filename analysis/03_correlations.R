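#!/usr/bin/env Rscript
# Stage 3 — correlation analyses.
#
# Extracts the four modelled accessibility values at the cluster points and
# computes (i) the between-method Spearman matrix and (ii) Spearman
# correlations between perceived and modelled accessibility, overall and
# stratified by urban/rural, motorized/non-motorized, their crosses, and
# region. Also writes smoothed PA-MA curves for plotting.

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
ma <- as.data.frame(lapply(surfaces, extract_at_points,
                           x = clusters$x, y = clusters$y))

mm <- method_correlation_matrix(ma)
cat("Between-method |r_s| (sign in parentheses):\n")
print(round(mm, 3))
write.csv(cbind(method = rownames(mm), as.data.frame(mm)),
          "results/method_correlations.csv", row.names = FALSE)

pa_ma <- stratified_pa_ma(clusters, ma)
write.csv(pa_ma, "results/pa_ma_correlations.csv", row.names = FALSE)
key <- pa_ma[pa_ma$stratum %in% c("all", "urban", "rural",
                                  "motorized", "non_motorized"), ]
cat("\nPA-MA |r_s| by stratum:\n")
print(reshape(key[, c("method", "stratum", "rho_abs")],
              idvar = "method", timevar = "stratum", direction = "wide"),
      digits = 3)

pa <- perceived_access(clusters)
curves <- do.call(rbind, lapply(names(ma), function(m) {
  cv <- loess_curve(ma[[m]], pa, span = 0.75)
  cv$method <- m
  cv
}))
write.csv(curves, "results/pa_ma_loess_curves.csv", row.names = FALSE)
cat("\nTables written to results/\n")
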