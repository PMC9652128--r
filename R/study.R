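#' Study configuration
#'
#' Bundles every knob of the end-to-end synthetic study: the landscape and
#' cluster generators, the accessibility methods to run, the kernel and
#' connectivity settings, the strata, the population class breaks, the
#' displacement design, and a single master seed. Stage seeds are derived
#' from the master seed by a fixed counter scheme (`seed + 1` landscape,
#' `+ 2` facilities, `+ 3` clusters, `+ 4` displacement), so every stage is
#' reproducible in isolation.
#'
#' @param landscape a [landscape_config()].
#' @param clustergen a [cluster_gen_config()].
#' @param n_facilities number of facilities.
#' @param methods subset of `c("ED", "CD_M", "CD_W", "KD")`.
#' @param kernel a [kernel_config()].
#' @param connectivity 8 or 16, for the cost-distance graph.
#' @param strata strata passed to [stratified_pa_ma()].
#' @param ed_breaks,cd_breaks class boundaries for the population summaries
#'   (meters for ED, minutes for CD).
#' @param displacement a [displacement_config()].
#' @param n_replicates displacement replicates (default 30).
#' @param admin_tiles admin tiling of the extent.
#' @param seed master seed.
#' @return a `study_config`.
#' @export
study_config <- function(landscape = landscape_config(),
                         clustergen = cluster_gen_config(),
                         n_facilities = 80,
                         methods = c("ED", "CD_M", "CD_W", "KD"),
                         kernel = kernel_config(),
                         connectivity = 8,
                         strata = c("all", "urban_rural", "motorized",
                                    "urban_rural_x_motorized", "region"),
                         ed_breaks = c(1000, 5000, 10000, 15000),
                         cd_breaks = c(10, 30, 60, 120),
                         displacement = displacement_config(),
                         n_replicates = 30,
                         admin_tiles = c(4, 3),
                         seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_replicates >= 1)
  structure(as.list(environment()), class = "study_config")
}

#' Run the full accessibility-validation study
#'
#' Orchestrates the complete pipeline on synthetic data: landscape and
#' facility generation, the requested accessibility surfaces, cluster
#' generation with a known logistic link, extraction at cluster points, the
#' between-method Spearman matrix, stratified PA-MA correlations, the
#' displacement replication study, and population-by-class summaries (ED and
#' CD methods only). When `out_dir` is given, every result table is written
#' as CSV, the surfaces as ESRI ASCII rasters, and a JSON manifest records
#' the seeds and parameters needed to regenerate every number.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional output directory.
#' @return (invisibly when writing) a list with `surfaces`, `clusters`,
#'   `truth`, `ma` (extracted values), `method_matrix`, `pa_ma`,
#'   `replication`, `pop_class`, `manifest`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  seed <- cfg$seed

  land <- make_landscape(cfg$landscape, seed = seed + 1)
  fac <- make_facilities(land$population, cfg$n_facilities,
                         "population_weighted", seed = seed + 2)
  template <- land$population

  surfaces <- list()
  if ("ED" %in% cfg$methods)
    surfaces$ED <- euclidean_surface(template, fac)
  if ("CD_M" %in% cfg$methods)
    surfaces$CD_M <- cost_distance_surface(land$motor, fac, cfg$connectivity)
  if ("CD_W" %in% cfg$methods)
    surfaces$CD_W <- cost_distance_surface(land$walk, fac, cfg$connectivity)
  if ("KD" %in% cfg$methods)
    surfaces$KD <- kernel_density_surface(template, fac, cfg$kernel)

  driving <- if (!is.null(surfaces$ED)) surfaces$ED else surfaces[[1]]
  admin <- tile_admin(template, cfg$admin_tiles[1], cfg$admin_tiles[2])
  cl <- make_clusters(cfg$clustergen, driving, template, region = admin,
                      seed = seed + 3)
  clusters <- cl$clusters

  ma <- as.data.frame(lapply(surfaces, extract_at_points,
                             x = clusters$x, y = clusters$y))
  method_matrix <- method_correlation_matrix(ma)
  pa_ma <- stratified_pa_ma(clusters, ma, strata = cfg$strata)

  replication <- replicate_displacement_study(
    clusters, surfaces, cfg$displacement, R = cfg$n_replicates,
    seed = seed + 4, admin = NULL, by_region = TRUE)

  pop_class <- list()
  for (m in intersect(c("ED", "CD_M", "CD_W"), names(surfaces))) {
    breaks <- if (m == "ED") cfg$ed_breaks else cfg$cd_breaks
    tab <- population_by_class(surfaces[[m]], land$population, breaks)
    tab$method <- m
    pop_class[[m]] <- tab
  }
  pop_class <- if (length(pop_class)) do.call(rbind, pop_class) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("hfaccess")),
    master_seed = seed,
    stage_seeds = list(landscape = seed + 1, facilities = seed + 2,
                       clusters = seed + 3, displacement = seed + 4),
    methods = cfg$methods,
    skipped_methods = setdiff(c("ED", "CD_M", "CD_W", "KD"), cfg$methods),
    n_facilities = cfg$n_facilities,
    connectivity = cfg$connectivity,
    kernel = unclass(cfg$kernel),
    displacement = unclass(cfg$displacement),
    n_replicates = cfg$n_replicates,
    landscape = unclass(cfg$landscape),
    clustergen = unclass(cfg$clustergen),
    outputs = c("surfaces", "method_correlations", "pa_ma_correlations",
                "displacement_replicates", "population_classes"))

  out <- list(surfaces = surfaces, facilities = fac, clusters = clusters,
              truth = cl$truth, ma = ma, method_matrix = method_matrix,
              pa_ma = pa_ma, replication = replication,
              pop_class = pop_class, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(surfaces))
      write_raster(surfaces[[m]]$grid,
                   file.path(out_dir, paste0("surface_", tolower(m), ".asc")))
    mm <- as.data.frame(method_matrix)
    mm <- cbind(method = rownames(method_matrix), mm)
    utils::write.csv(mm, file.path(out_dir, "method_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(pa_ma, file.path(out_dir, "pa_ma_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(replication$replicates,
                     file.path(out_dir, "displacement_replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(replication$summary,
                     file.path(out_dir, "displacement_summary.csv"),
                     row.names = FALSE)
    if (!is.null(pop_class))
      utils::write.csv(pop_class,
                       file.path(out_dir, "population_classes.csv"),
                       row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
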