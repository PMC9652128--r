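#' Synthetic landscape configuration
#'
#' Parameters of the generated study landscape: a square projected grid with
#' uniform walking friction, a motorized friction surface where random road
#' polylines are much faster than the off-road background, impassable
#' barrier strips (rivers/ridges), and a population surface made of Gaussian
#' "town" blobs over a low rural floor.
#'
#' Defaults describe a 200 x 200 km region at 1 km resolution: walking at
#' 5 km/h (0.012 min/m), roads at 50 km/h (0.0012 min/m), 6 roads, 3
#' barriers and 8 towns.
#'
#' @param nrows,ncols grid dimensions.
#' @param cell_size cell edge in meters.
#' @param base_walk_friction off-road friction, min/m.
#' @param road_friction on-road friction, min/m (must be faster than
#'   walking).
#' @param n_roads,n_barriers,n_towns feature counts.
#' @param pop_floor uniform rural population per cell.
#' @param town_pop peak population of a town blob.
#' @param town_sd_cells Gaussian radius of a town, in cells.
#' @return a `landscape_config`.
#' @export
landscape_config <- function(nrows = 200, ncols = 200, cell_size = 1000,
                             base_walk_friction = 0.012,
                             road_friction = 0.0012,
                             n_roads = 6, n_barriers = 3, n_towns = 8,
                             pop_floor = 5, town_pop = 5000,
                             town_sd_cells = 6) {
  stopifnot(base_walk_friction > 0, road_friction > 0,
            road_friction < base_walk_friction)
  structure(as.list(environment()), class = "landscape_config")
}

# mark cells crossed by the segment (r0,c0)-(r1,c1) (supercover sampling)
rasterize_segment <- function(mask, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) * 3 + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  mask[cbind(rr, cc)] <- TRUE
  mask
}

#' Generate a synthetic landscape
#'
#' Builds the walking and motorized friction surfaces and the population
#' grid described by a [landscape_config()]. Walking friction is the uniform
#' base value everywhere; motorized friction equals the base off-road and
#' the (faster) road value on rasterized random road polylines; barrier
#' strips are impassable (`Inf`) in both. Population is a mixture of
#' Gaussian town blobs over a uniform floor; barrier cells hold no
#' population.
#'
#' @param cfg a [landscape_config()].
#' @param seed integer seed.
#' @return list with `walk` and `motor` ([friction_surface()]), `population`
#'   ([raster_grid()]) and `towns` (data.frame of blob centers and weights).
#' @export
make_landscape <- function(cfg = landscape_config(), seed = 1) {
  set.seed(seed)
  nr <- cfg$nrows; nc <- cfg$ncols
  walk <- matrix(cfg$base_walk_friction, nr, nc)
  motor <- matrix(cfg$base_walk_friction, nr, nc)

  edge_point <- function() {
    side <- sample.int(4, 1)
    switch(side,
           c(1L, sample.int(nc, 1)),        # north edge
           c(nr, sample.int(nc, 1)),        # south edge
           c(sample.int(nr, 1), 1L),        # west edge
           c(sample.int(nr, 1), nc))        # east edge
  }
  road_mask <- matrix(FALSE, nr, nc)
  if (cfg$n_roads > 0) for (i in seq_len(cfg$n_roads)) {
    p1 <- edge_point(); p2 <- edge_point()
    road_mask <- rasterize_segment(road_mask, p1[1], p1[2], p2[1], p2[2])
  }
  motor[road_mask] <- cfg$road_friction

  barrier_mask <- matrix(FALSE, nr, nc)
  if (cfg$n_barriers > 0) for (i in seq_len(cfg$n_barriers)) {
    # a partial strip: horizontal or vertical band covering ~60% of the span
    if (stats::runif(1) < 0.5) {
      r <- sample(round(0.2 * nr):round(0.8 * nr), 1)
      c0 <- sample.int(nc, 1); len <- round(0.6 * nc)
      cc <- max(1, c0 - len %/% 2):min(nc, c0 + len %/% 2)
      barrier_mask[r, cc] <- TRUE
    } else {
      ci <- sample(round(0.2 * nc):round(0.8 * nc), 1)
      r0 <- sample.int(nr, 1); len <- round(0.6 * nr)
      rr <- max(1, r0 - len %/% 2):min(nr, r0 + len %/% 2)
      barrier_mask[rr, ci] <- TRUE
    }
  }
  barrier_mask <- barrier_mask & !road_mask   # roads bridge barriers
  walk[barrier_mask] <- Inf
  motor[barrier_mask] <- Inf

  towns <- data.frame(row = stats::runif(cfg$n_towns, 1, nr),
                      col = stats::runif(cfg$n_towns, 1, nc),
                      peak = cfg$town_pop * stats::runif(cfg$n_towns, 0.3, 1))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  pop <- matrix(cfg$pop_floor, nr, nc)
  for (t in seq_len(cfg$n_towns)) {
    d2 <- (rows - towns$row[t])^2 + (cols - towns$col[t])^2
    pop <- pop + towns$peak[t] * exp(-d2 / (2 * cfg$town_sd_cells^2))
  }
  pop[barrier_mask] <- 0

  y0 <- nr * cfg$cell_size
  g <- function(m) raster_grid(m, 0, y0, cfg$cell_size, "projected_m")
  list(walk = friction_surface(g(walk), "walking"),
       motor = friction_surface(g(motor), "motorized"),
       population = g(pop), towns = towns)
}

#' Sample facility locations
#'
#' Draws `n` distinct cells, with probability proportional to population
#' (`"population_weighted"`) or uniformly over populated cells
#' (`"uniform"`), and jitters each facility uniformly within its cell.
#'
#' @param population a [raster_grid()] of population counts.
#' @param n number of facilities.
#' @param placement `"population_weighted"` or `"uniform"`.
#' @param seed integer seed.
#' @return a [facility_set()].
#' @export
make_facilities <- function(population, n, placement = c("population_weighted",
                                                         "uniform"),
                            seed = 1) {
  placement <- match.arg(placement)
  stopifnot(n >= 1)
  set.seed(seed)
  pop <- population$values
  pop[is.na(pop)] <- 0
  eligible <- which(pop > 0)
  if (n > length(eligible))
    stop("n exceeds the number of populated cells", call. = FALSE)
  prob <- if (placement == "population_weighted") pop[eligible] else NULL
  cells <- eligible[sample.int(length(eligible), n, replace = FALSE,
                               prob = prob)]
  rc <- arrayInd(cells, dim(pop))
  ctr <- cell_center(population, rc[, 1], rc[, 2])
  jit <- population$cell_size * 0.499
  facility_set(ctr[, 1] + stats::runif(n, -jit, jit),
               ctr[, 2] + stats::runif(n, -jit, jit))
}

#' Survey-cluster generator configuration
#'
#' The generator draws cluster locations population-weighted, flags the
#' fraction of clusters in the densest locations as urban, assigns each
#' respondent a motorized-household flag by urban/rural probability, and
#' draws each respondent's "distance is an obstacle" answer from a logistic
#' model on the cluster's true modelled accessibility:
#' `P(yes) = plogis(a + b * MA/ma_scale + rural_shift * rural +
#' nonmotorized_shift * non_motorized + u)`, with a cluster-level random
#' effect `u ~ N(0, sd_u)` capturing the survey's extra between-cluster
#' variability.
#'
#' @param n_clusters number of clusters.
#' @param urban_fraction fraction of clusters flagged urban.
#' @param respondents_range integer range of respondents per cluster.
#' @param a,b logistic intercept and slope (slope per `ma_scale` units of
#'   the driving accessibility value; `ma_scale = 1000` means per km of
#'   Euclidean distance).
#' @param ma_scale divisor applied to the accessibility value before the
#'   linear predictor.
#' @param rural_shift,nonmotorized_shift additive shifts on the linear
#'   predictor for rural clusters and non-motorized respondents.
#' @param motorized_prob_urban,motorized_prob_rural per-respondent
#'   probability of a motorized household.
#' @param sd_u standard deviation of the cluster random effect.
#' @return a `cluster_gen_config`.
#' @export
cluster_gen_config <- function(n_clusters = 600, urban_fraction = 0.35,
                               respondents_range = c(15, 35),
                               a = -2, b = 0.18, ma_scale = 1000,
                               rural_shift = 0.7, nonmotorized_shift = 0.5,
                               motorized_prob_urban = 0.45,
                               motorized_prob_rural = 0.15,
                               sd_u = 0.5) {
  stopifnot(n_clusters >= 1, urban_fraction >= 0, urban_fraction <= 1,
            all(respondents_range >= 1), sd_u >= 0)
  structure(as.list(environment()), class = "cluster_gen_config")
}

#' Generate synthetic survey clusters
#'
#' Samples cluster locations from the population surface, computes each
#' cluster's true accessibility from the driving surface, and simulates
#' respondent-level motorized flags and yes/no answers under the logistic
#' model of [cluster_gen_config()]. Returns the aggregated cluster table
#' (the analysis never sees respondent-level data, matching the survey
#' design) together with the ground truth used to generate it.
#'
#' @param cfg a [cluster_gen_config()].
#' @param driving_surface an [access_surface()] the yes-probability depends
#'   on (typically the ED surface).
#' @param population a [raster_grid()] for location sampling and the urban
#'   flag.
#' @param region an optional function `(x, y) -> region id`, or an
#'   [admin_polygons()]; default splits the extent into 2 x 2 quadrants.
#' @param seed integer seed.
#' @return list with `clusters` (data.frame: id, x, y, urban, region_id,
#'   n_respondents, n_yes, n_motorized, n_yes_motorized) and `truth` (list:
#'   the config, per-cluster true accessibility `ma_true`, random effects
#'   `u`, and per-cluster yes-probabilities by subgroup).
#' @export
make_clusters <- function(cfg = cluster_gen_config(), driving_surface,
                          population, region = NULL, seed = 1) {
  set.seed(seed)
  n <- cfg$n_clusters
  pop <- population$values
  pop[is.na(pop)] <- 0
  eligible <- which(pop > 0)
  cells <- eligible[sample.int(length(eligible), n, replace = TRUE,
                               prob = pop[eligible])]
  rc <- arrayInd(cells, dim(pop))
  ctr <- cell_center(population, rc[, 1], rc[, 2])
  jit <- population$cell_size * 0.499
  x <- ctr[, 1] + stats::runif(n, -jit, jit)
  y <- ctr[, 2] + stats::runif(n, -jit, jit)

  # urban = densest locations, at the configured fraction
  dens <- pop[cells]
  urban <- rank(dens, ties.method = "first") > (1 - cfg$urban_fraction) * n

  region_id <- if (is.null(region)) {
    xmid <- population$x_origin + population$ncols * population$cell_size / 2
    ymid <- population$y_origin - population$nrows * population$cell_size / 2
    paste0("Q", 1 + (x > xmid) + 2 * (y > ymid))
  } else if (inherits(region, "admin_polygons")) {
    as.character(assign_polygon(region, x, y))
  } else {
    as.character(region(x, y))
  }

  ma_true <- extract_at_points(driving_surface, x, y)
  ma_true[!is.finite(ma_true)] <- max(ma_true[is.finite(ma_true)])
  u <- stats::rnorm(n, 0, cfg$sd_u)
  eta <- cfg$a + cfg$b * ma_true / cfg$ma_scale +
    cfg$rural_shift * as.numeric(!urban) + u
  p_mot <- stats::plogis(eta)
  p_non <- stats::plogis(eta + cfg$nonmotorized_shift)

  n_resp <- sample(cfg$respondents_range[1]:cfg$respondents_range[2], n,
                   replace = TRUE)
  pm <- ifelse(urban, cfg$motorized_prob_urban, cfg$motorized_prob_rural)
  n_mot <- stats::rbinom(n, n_resp, pm)
  yes_mot <- stats::rbinom(n, n_mot, p_mot)
  yes_non <- stats::rbinom(n, n_resp - n_mot, p_non)

  clusters <- data.frame(
    id = seq_len(n), x = x, y = y, urban = urban, region_id = region_id,
    n_respondents = n_resp, n_yes = yes_mot + yes_non,
    n_motorized = n_mot, n_yes_motorized = yes_mot)
  truth <- list(config = cfg, ma_true = ma_true, u = u,
                p_yes_motorized = p_mot, p_yes_non_motorized = p_non)
  list(clusters = clusters, truth = truth)
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates a landscape, facilities, the driving Euclidean surface,
#' clusters and a rectangular admin tiling, and writes them as plain-text
#' files (ESRI ASCII rasters, CSV points/clusters, GeoJSON polygons, JSON
#' ground truth). Rerunning with the same seed reproduces every file
#' byte-for-byte.
#'
#' @param dir output directory (created if needed).
#' @param landscape a [landscape_config()].
#' @param clustergen a [cluster_gen_config()].
#' @param n_facilities number of facilities.
#' @param admin_tiles `c(nx, ny)` tiling of the extent into admin polygons.
#' @param seed master seed; stage seeds are `seed + 1..4`.
#' @return invisibly, the list of generated objects.
#' @export
make_study_bundle <- function(dir, landscape = landscape_config(),
                              clustergen = cluster_gen_config(),
                              n_facilities = 80, admin_tiles = c(4, 3),
                              seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- make_landscape(landscape, seed = seed + 1)
  fac <- make_facilities(land$population, n_facilities,
                         "population_weighted", seed = seed + 2)
  ed <- euclidean_surface(land$population, fac)
  admin <- tile_admin(land$population, admin_tiles[1], admin_tiles[2])
  cl <- make_clusters(clustergen, ed, land$population, region = admin,
                      seed = seed + 3)

  write_raster(land$walk$grid, file.path(dir, "friction_walk.asc"))
  write_raster(land$motor$grid, file.path(dir, "friction_motor.asc"))
  write_raster(land$population, file.path(dir, "population.asc"))
  write_facilities_csv(fac, file.path(dir, "facilities.csv"))
  write_facilities_geojson(fac, file.path(dir, "facilities.geojson"))
  utils::write.csv(cl$clusters, file.path(dir, "clusters.csv"),
                   row.names = FALSE)
  write_admin_geojson(admin, file.path(dir, "admin.geojson"))
  jsonlite::write_json(
    list(seed = seed,
         landscape = unclass(landscape),
         clustergen = unclass(clustergen),
         n_facilities = n_facilities,
         ma_true = cl$truth$ma_true, u = cl$truth$u),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(landscape = land, facilities = fac, ed = ed,
                 admin = admin, clusters = cl$clusters, truth = cl$truth))
}

#' Rectangular admin tiling of a grid extent
#'
#' @param grid a [raster_grid()].
#' @param nx,ny number of tiles along x and y.
#' @return an [admin_polygons()] with `nx * ny` rectangles.
#' @export
tile_admin <- function(grid, nx = 4, ny = 3) {
  x0 <- grid$x_origin
  x1 <- grid$x_origin + grid$ncols * grid$cell_size
  y1 <- grid$y_origin
  y0 <- grid$y_origin - grid$nrows * grid$cell_size
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  rings <- list(); ids <- character(0)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    rings[[length(rings) + 1L]] <- list(cbind(
      c(xs[i], xs[i + 1], xs[i + 1], xs[i]),
      c(ys[j], ys[j], ys[j + 1], ys[j + 1])))
    ids <- c(ids, sprintf("A%02d", length(ids) + 1L))
  }
  admin_polygons(rings, id = ids)
}
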