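test_that("landscape generation honors its construction rules", {
  cfg <- landscape_config(nrows = 40, ncols = 40, n_roads = 0, n_barriers = 0)
  land <- make_landscape(cfg, seed = 61)
  expect_true(all(land$motor$grid$values == cfg$base_walk_friction))
  expect_true(all(land$walk$grid$values == cfg$base_walk_friction))
  expect_true(all(land$population$values >= 0))

  cfg2 <- landscape_config(nrows = 40, ncols = 40, n_roads = 4, n_barriers = 2)
  land2 <- make_landscape(cfg2, seed = 62)
  v <- land2$motor$grid$values
  expect_true(any(v == cfg2$road_friction))            # roads exist
  expect_true(all(v[is.finite(v)] %in%
                    c(cfg2$road_friction, cfg2$base_walk_friction)))
  expect_lt(cfg2$road_friction, cfg2$base_walk_friction)
  expect_true(any(is.infinite(land2$walk$grid$values)))  # barriers exist
  # reproducibility
  land3 <- make_landscape(cfg2, seed = 62)
  expect_identical(land2$motor$grid$values, land3$motor$grid$values)
  expect_identical(land2$population$values, land3$population$values)
})

test_that("facility placement is population-weighted and reproducible", {
  pop1 <- raster_grid(matrix(c(0, 0, 0, 10), 2, 2), 0, 2000, 1000)
  f1 <- make_facilities(pop1, 1, seed = 63)
  expect_equal(unlist(point_to_cell(pop1, f1$x, f1$y)[1, 1:2]),
               c(row = 2, col = 2))
  expect_error(make_facilities(pop1, 2), "exceeds")

  # two-blob map: facility counts track the population shares
  pop <- matrix(0, 100, 100)
  pop[5:44, 5:44] <- 30      # blob A: weight 3x blob B, equal cell counts
  pop[55:94, 55:94] <- 10
  g <- raster_grid(pop, 0, 100000, 1000)
  f <- make_facilities(g, 500, seed = 64)
  cells <- point_to_cell(g, f$x, f$y)
  in_a <- mean(cells$row <= 50)
  p_a <- 0.75
  se <- sqrt(p_a * (1 - p_a) / 500)
  expect_gt(in_a, p_a - 3 * se)   # inside the (approximate) 99% band
  expect_lt(in_a, p_a + 3 * se)

  f2 <- make_facilities(g, 500, seed = 64)
  expect_identical(f, f2)
})

test_that("a flat link yields the analytic mean PA", {
  land <- make_landscape(landscape_config(nrows = 50, ncols = 50), seed = 65)
  fac <- make_facilities(land$population, 15, seed = 66)
  ed <- euclidean_surface(land$population, fac)
  cfg <- cluster_gen_config(n_clusters = 1000, a = -1, b = 0,
                            rural_shift = 0, nonmotorized_shift = 0,
                            sd_u = 0, respondents_range = c(25, 25))
  cl <- make_clusters(cfg, ed, land$population, seed = 67)
  pa <- perceived_access(cl$clusters)
  p_true <- plogis(-1)
  se <- sqrt(p_true * (1 - p_true) / (1000 * 25))
  expect_lt(abs(mean(pa) - p_true), 3 * se)
})

test_that("a positive link drives a positive PA-ED rank correlation", {
  land <- make_landscape(landscape_config(nrows = 80, ncols = 80), seed = 68)
  fac <- make_facilities(land$population, 30, seed = 69)
  ed <- euclidean_surface(land$population, fac)
  cl <- make_clusters(cluster_gen_config(n_clusters = 1000, b = 0.3),
                      ed, land$population, seed = 70)
  ma <- extract_at_points(ed, cl$clusters$x, cl$clusters$y)
  s <- spearman_cor(perceived_access(cl$clusters), ma)
  expect_gt(s$rho, 0)
  expect_lt(s$p_value, 0.001)
})

test_that("the non-motorized shift raises the non-motorized subgroup PA", {
  land <- make_landscape(landscape_config(nrows = 50, ncols = 50), seed = 71)
  fac <- make_facilities(land$population, 15, seed = 72)
  ed <- euclidean_surface(land$population, fac)
  cl <- make_clusters(cluster_gen_config(n_clusters = 800,
                                         nonmotorized_shift = 0.8),
                      ed, land$population, seed = 73)$clusters
  pm <- suppressWarnings(perceived_access(cl, "motorized"))
  pn <- suppressWarnings(perceived_access(cl, "non_motorized"))
  expect_gt(mean(pn, na.rm = TRUE), mean(pm, na.rm = TRUE))
})

test_that("maximum likelihood refit recovers the generating slope", {
  land <- make_landscape(landscape_config(nrows = 80, ncols = 80), seed = 74)
  fac <- make_facilities(land$population, 30, seed = 75)
  ed <- euclidean_surface(land$population, fac)
  b_true <- 0.18
  cfg <- cluster_gen_config(n_clusters = 2000, b = b_true, sd_u = 0)
  cl <- make_clusters(cfg, ed, land$population, seed = 76)
  d <- cl$clusters
  ma_km <- cl$truth$ma_true / 1000
  # respondent groups: motorized and non-motorized counts per cluster
  long <- rbind(
    data.frame(yes = d$n_yes_motorized, n = d$n_motorized,
               ma = ma_km, rural = !d$urban, nonmot = 0),
    data.frame(yes = d$n_yes - d$n_yes_motorized,
               n = d$n_respondents - d$n_motorized,
               ma = ma_km, rural = !d$urban, nonmot = 1))
  long <- long[long$n > 0, ]
  fit <- glm(cbind(yes, n - yes) ~ ma + rural + nonmot,
             family = binomial, data = long)
  b_hat <- coef(fit)[["ma"]]
  expect_lt(abs(b_hat - b_true) / b_true, 0.15)
})

test_that("study bundles are byte-identical under a fixed seed and load end-to-end", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  lc <- landscape_config(nrows = 40, ncols = 40, n_towns = 4)
  cc <- cluster_gen_config(n_clusters = 100)
  make_study_bundle(dir1, lc, cc, n_facilities = 15, seed = 77)
  make_study_bundle(dir2, lc, cc, n_facilities = 15, seed = 77)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # every pipeline stage consumes the bundle from disk
  walk <- friction_surface(read_raster(file.path(dir1, "friction_walk.asc")),
                           "walking")
  pop <- read_raster(file.path(dir1, "population.asc"))
  fac <- read_facilities_csv(file.path(dir1, "facilities.csv"))
  cl <- read.csv(file.path(dir1, "clusters.csv"))
  admin <- read_admin_geojson(file.path(dir1, "admin.geojson"))
  ed <- euclidean_surface(pop, fac)
  cdw <- cost_distance_surface(walk, fac)
  ma <- data.frame(ED = extract_at_points(ed, cl$x, cl$y),
                   CD_W = extract_at_points(cdw, cl$x, cl$y))
  res <- stratified_pa_ma(cl, ma, strata = c("all", "region"))
  expect_true(nrow(res) >= 2)
  tab <- population_by_class(ed, pop, c(1000, 5000, 15000))
  expect_equal(sum(tab$share), 1, tolerance = 1e-12)
  expect_true(all(!is.na(assign_polygon(admin, cl$x, cl$y))))
})

test_that("a 12-tile admin split yields 12 per-region strata", {
  dir <- withr::local_tempdir()
  b <- make_study_bundle(dir, landscape_config(nrows = 60, ncols = 60),
                         cluster_gen_config(n_clusters = 600),
                         n_facilities = 20, admin_tiles = c(4, 3), seed = 78)
  expect_equal(length(b$admin$id), 12)
  ma <- data.frame(ED = extract_at_points(b$ed, b$clusters$x, b$clusters$y))
  res <- suppressMessages(
    stratified_pa_ma(b$clusters, ma, strata = "region"))
  # every sufficiently populated tile appears; with 600 clusters all 12 should
  expect_equal(sort(unique(res$stratum)),
               sort(paste0("region:", b$admin$id)))
})
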