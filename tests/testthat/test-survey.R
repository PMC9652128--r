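clusters_fixture <- function(n = 50, seed = 21) {
  set.seed(seed)
  n_resp <- sample(15:30, n, replace = TRUE)
  n_mot <- rbinom(n, n_resp, 0.3)
  yes_mot <- rbinom(n, n_mot, 0.3)
  yes_non <- rbinom(n, n_resp - n_mot, 0.5)
  data.frame(id = 1:n, x = runif(n, 0, 1e4), y = runif(n, 0, 1e4),
             urban = runif(n) < 0.4,
             region_id = sample(c("A", "B", "C"), n, replace = TRUE),
             n_respondents = n_resp, n_yes = yes_mot + yes_non,
             n_motorized = n_mot, n_yes_motorized = yes_mot)
}

test_that("perceived access is the yes-proportion, by subgroup", {
  cl <- data.frame(n_respondents = c(20, 10, 8, 5),
                   n_yes = c(5, 0, 8, 3),
                   n_motorized = c(10, 0, 4, 5),
                   n_yes_motorized = c(2, 0, 4, 3))
  expect_equal(perceived_access(cl), c(0.25, 0, 1, 0.6))
  expect_warning(pm <- perceived_access(cl, "motorized"), "zero respondents")
  expect_equal(pm, c(0.2, NA, 1, 0.6))
  expect_warning(pn <- perceived_access(cl, "non_motorized"), "zero")
  expect_equal(pn, c(0.3, 0, 1, NA))
  bad <- data.frame(n_respondents = 5, n_yes = 7,
                    n_motorized = 0, n_yes_motorized = 0)
  expect_error(perceived_access(bad), "exceed")
})

test_that("spearman matches perfect monotone cases and the tie oracle", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:4, c(8, 6, 4, 2))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  expect_equal(spearman_cor(x, y)$rho, brute_spearman(x, y))
  set.seed(22)
  for (i in 1:10) {
    xs <- sample(1:6, 12, replace = TRUE)
    ys <- sample(1:6, 12, replace = TRUE)
    if (length(unique(xs)) < 2 || length(unique(ys)) < 2) next
    expect_equal(spearman_cor(xs, ys)$rho, brute_spearman(xs, ys))
    # cross-check against the standard implementation
    expect_equal(spearman_cor(xs, ys)$rho,
                 suppressWarnings(cor(xs, ys, method = "spearman")))
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3)$rho, base)
  expect_equal(spearman_cor(exp(x), exp(y))$rho, base)
})

test_that("constant input yields an undefined correlation, not a number", {
  s <- spearman_cor(rep(1, 10), 1:10)
  expect_true(s$undefined)
  expect_true(is.na(s$rho))
  s2 <- spearman_cor(1:2, 2:1)
  expect_true(s2$undefined)   # fewer than 3 pairs
})

test_that("spearman p-value follows the t approximation", {
  set.seed(24)
  x <- rnorm(30); y <- x + rnorm(30, sd = 2)
  s <- spearman_cor(x, y)
  tstat <- s$rho * sqrt((s$n - 2) / (1 - s$rho^2))
  expect_equal(s$p_value, 2 * pt(-abs(tstat), s$n - 2))
})

test_that("method correlation matrix is symmetric, unit-diagonal, sign-aware", {
  set.seed(25)
  ed <- runif(60, 0, 2e4)
  ma <- data.frame(ED = ed, CD_W = ed * 0.012 + rnorm(60),
                   DUP = ed, KD = exp(-ed / 5e3))
  m <- method_correlation_matrix(ma)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(ED = 1, CD_W = 1, DUP = 1, KD = 1))
  expect_equal(m["ED", "DUP"], 1)               # duplicated pair
  expect_equal(attr(m, "sign")["ED", "KD"], -1) # KD anti-correlated
  expect_true(all(m >= 0 & m <= 1))
})

test_that("the all-clusters stratum equals the unstratified correlation", {
  cl <- clusters_fixture()
  ma <- data.frame(ED = runif(50, 0, 2e4))
  res <- stratified_pa_ma(cl, ma, strata = "all")
  direct <- spearman_cor(perceived_access(cl), ma$ED)
  expect_equal(res$rho_abs, abs(direct$rho))
  expect_equal(res$p_value, direct$p_value)
  expect_equal(res$n, 50)
})

test_that("undersized strata are skipped with a message", {
  cl <- clusters_fixture()
  cl$region_id <- c(rep("big", 48), "tiny", "tiny")
  ma <- data.frame(ED = runif(50, 0, 2e4))
  expect_message(res <- stratified_pa_ma(cl, ma, strata = "region"),
                 "tiny.*skipped|skipped")
  expect_false("region:tiny" %in% res$stratum)
  expect_true("region:big" %in% res$stratum)
})

test_that("motorized strata use subgroup-specific PA by default", {
  cl <- clusters_fixture()
  ma <- data.frame(ED = runif(50, 0, 2e4))
  res <- stratified_pa_ma(cl, ma, strata = "motorized")
  keep <- cl$n_motorized > 0
  direct <- spearman_cor(
    suppressWarnings(perceived_access(cl, "motorized"))[keep], ma$ED[keep])
  expect_equal(res$rho_abs[res$stratum == "motorized"], abs(direct$rho))
  # crosses exist when requested
  res2 <- stratified_pa_ma(cl, ma, strata = "urban_rural_x_motorized")
  expect_setequal(unique(res2$stratum),
                  c("urban_motorized", "urban_non_motorized",
                    "rural_motorized", "rural_non_motorized"))
})

test_that("PA-ED rank correlation grows with the generating link slope", {
  rhos <- vapply(c(0, 0.15, 0.5), function(b) {
    land <- make_landscape(landscape_config(nrows = 60, ncols = 60), seed = 31)
    fac <- make_facilities(land$population, 25, seed = 32)
    ed <- euclidean_surface(land$population, fac)
    cl <- make_clusters(cluster_gen_config(n_clusters = 400, b = b, sd_u = 0.3),
                        ed, land$population, seed = 33)
    ma <- extract_at_points(ed, cl$clusters$x, cl$clusters$y)
    spearman_cor(perceived_access(cl$clusters), ma)$rho
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_lt(abs(rhos[1]), 0.15)
  expect_gt(rhos[3], 0.5)
})

test_that("loess curve reproduces constants and straight lines", {
  x <- seq(0, 10, length.out = 40)
  flat <- loess_curve(x, rep(2.5, 40))
  expect_true(all(abs(flat$y - 2.5) < 1e-8))
  lin <- loess_curve(x, 2 * x, span = 0.5)
  interior <- lin$x > 1 & lin$x < 9
  expect_true(all(abs(lin$y - 2 * lin$x)[interior] < 1e-6))
  expect_error(loess_curve(1:5, 1:5), "at least 10")
})

test_that("loess recovers a monotone trend from noisy logistic data", {
  set.seed(26)
  x <- runif(300, 0, 20)
  y <- plogis(-2 + 0.4 * x) + rnorm(300, sd = 0.05)
  cv <- loess_curve(x, y, span = 0.75)
  # isotonic check: the fitted curve is monotone non-decreasing (small slack)
  expect_true(all(diff(cv$y) > -1e-3))
})

test_that("population classes conserve mass and match brute-force binning", {
  set.seed(27)
  g <- raster_grid(matrix(runif(400, 0, 2e4), 20, 20), 0, 20000, 1000)
  ed <- access_surface(g, "ED", "meters")
  pop <- raster_grid(matrix(rpois(400, 30), 20, 20), 0, 20000, 1000)
  breaks <- c(1000, 5000, 10000, 15000)
  tab <- population_by_class(ed, pop, breaks)
  expect_equal(sum(tab$share), 1, tolerance = 1e-12)
  # brute-force per-cell classification
  acc <- as.vector(g$values); p <- as.vector(pop$values)
  edges <- c(-Inf, breaks, Inf)
  for (k in seq_len(length(edges) - 1)) {
    inb <- acc > edges[k] & acc <= edges[k + 1]
    expect_equal(tab$population[k], sum(p[inb]))
  }
})

test_that("population classes handle point masses, nodata and errors", {
  g <- raster_grid(matrix(c(500, NA, 2e4, 3e4), 2, 2), 0, 2000, 1000)
  ed <- access_surface(g, "ED", "meters")
  pop <- raster_grid(matrix(c(100, 50, 0, 0), 2, 2), 0, 2000, 1000)
  tab <- population_by_class(ed, pop, c(1000, 5000, 15000))
  expect_equal(tab$share[tab$class == "<=1000"], 100 / 150)
  expect_equal(tab$share[tab$class == "unclassified"], 50 / 150)
  expect_equal(sum(tab$share), 1, tolerance = 1e-12)

  kd <- access_surface(g, "KD", "dimensionless")
  expect_error(population_by_class(kd, pop, c(1, 2)), "KD")
  empty <- raster_grid(matrix(0, 2, 2), 0, 2000, 1000)
  expect_error(population_by_class(ed, empty, c(1000)), "empty|zero")
  expect_error(population_by_class(ed, pop, c(5000, 1000)), "increasing")
})
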