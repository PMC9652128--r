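#' Geomasking displacement configuration
#'
#' Parameters of the DHS-style cluster displacement: urban clusters move a
#' uniform random distance up to 2 km in a uniform random direction, rural
#' clusters up to 5 km, and 1% of rural clusters (Bernoulli per cluster)
#' have their maximum radius replaced by 10 km. Optionally the displaced
#' point is constrained, by rejection sampling, to the administrative
#' polygon containing the original point.
#'
#' @param urban_max,rural_max,rural_extra_max maximum displacement radii in
#'   meters (defaults 2,000 / 5,000 / 10,000).
#' @param rural_extra_prob probability a rural cluster gets the extended
#'   radius (default 0.01).
#' @param constrain_to_admin constrain displaced points to the source
#'   polygon?
#' @param max_rejection_tries rejection-sampling budget per point before the
#'   original point is kept with a warning.
#' @return a `displacement_config`.
#' @export
displacement_config <- function(urban_max = 2000, rural_max = 5000,
                                rural_extra_prob = 0.01,
                                rural_extra_max = 10000,
                                constrain_to_admin = FALSE,
                                max_rejection_tries = 1000) {
  stopifnot(urban_max >= 0, rural_max >= 0, rural_extra_max >= 0,
            rural_extra_prob >= 0, rural_extra_prob <= 1,
            max_rejection_tries >= 1)
  structure(list(urban_max = urban_max, rural_max = rural_max,
                 rural_extra_prob = rural_extra_prob,
                 rural_extra_max = rural_extra_max,
                 constrain_to_admin = constrain_to_admin,
                 max_rejection_tries = max_rejection_tries),
            class = "displacement_config")
}

#' Displace cluster points
#'
#' Applies the geomasking displacement to each point: direction uniform on
#' \[0, 2*pi*), distance uniform on \[0, D\] where D is the class maximum
#' (with the 1% rural extension drawn per cluster). With
#' `constrain_to_admin`, draws are rejected until the displaced point lies
#' in the same polygon as its source; after `max_rejection_tries` failures
#' the original point is kept with a warning. Coordinates are treated as
#' planar meters.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param x,y source coordinates (meters).
#' @param urban logical vector, same length.
#' @param cfg a [displacement_config()].
#' @param admin an [admin_polygons()] (required when `constrain_to_admin`).
#' @return data.frame with `x`, `y` (displaced), `distance` (realised
#'   displacement in meters) and `max_radius` (the per-point cap D).
#' @export
displace_points <- function(x, y, urban, cfg = displacement_config(),
                            admin = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(urban) == n)
  extra <- !urban & (stats::runif(n) < cfg$rural_extra_prob)
  D <- ifelse(urban, cfg$urban_max,
              ifelse(extra, cfg$rural_extra_max, cfg$rural_max))
  if (cfg$constrain_to_admin) {
    if (is.null(admin))
      stop("constrain_to_admin = TRUE requires `admin` polygons", call. = FALSE)
    home <- assign_polygon(admin, x, y)
    if (anyNA(home))
      stop(sum(is.na(home)),
           " point(s) lie in no admin polygon; cannot constrain", call. = FALSE)
  }
  theta <- stats::runif(n, 0, 2 * pi)
  d <- stats::runif(n, 0, D)
  nx <- x + d * cos(theta)
  ny <- y + d * sin(theta)
  if (cfg$constrain_to_admin) {
    cur <- assign_polygon(admin, nx, ny)
    pending <- which(is.na(cur) | cur != home)
    tries <- 0L
    while (length(pending) && tries < cfg$max_rejection_tries) {
      th2 <- stats::runif(length(pending), 0, 2 * pi)
      d2 <- stats::runif(length(pending), 0, D[pending])
      nx[pending] <- x[pending] + d2 * cos(th2)
      ny[pending] <- y[pending] + d2 * sin(th2)
      d[pending] <- d2
      inpoly <- assign_polygon(admin, nx[pending], ny[pending])
      ok <- !is.na(inpoly) & inpoly == home[pending]
      pending <- pending[!ok]
      tries <- tries + 1L
    }
    if (length(pending)) {
      warning(length(pending), " point(s) kept at their original location ",
              "after exhausting rejection tries")
      nx[pending] <- x[pending]; ny[pending] <- y[pending]; d[pending] <- 0
    }
  }
  data.frame(x = nx, y = ny, distance = d, max_radius = D)
}

#' Displacement replication study
#'
#' Quantifies how the geomasking displacement perturbs the PA-MA Spearman
#' correlations: for each of `R` replicates, every cluster is re-displaced
#' from its provided coordinates, the accessibility surfaces are re-sampled
#' at the displaced points, and the Spearman correlation between the
#' perceived-accessibility index and each method is recomputed (per region
#' when `by_region`). Replicate `r` uses the derived seed
#' `(seed + r * 9973) mod (2^31 - 1)` with clusters drawn in table order, so
#' reruns are bit-identical.
#'
#' @param clusters cluster table (columns `id`, `x`, `y`, `urban`,
#'   `region_id`, `n_respondents`, `n_yes`, ...).
#' @param surfaces named list of [access_surface()] objects.
#' @param cfg a [displacement_config()].
#' @param R number of replicates (the study design uses 30).
#' @param seed integer master seed.
#' @param admin optional [admin_polygons()] for constrained displacement.
#' @param by_region also compute per-region correlations?
#' @return list with `replicates` (data.frame: replicate, method, region,
#'   rho_abs, sign, p_value, n), `baseline` (same shape, replicate 0, from
#'   the undisplaced coordinates) and `summary` (per method x region: mean,
#'   min, max of rho_abs and `share_attenuated`, the share of replicates
#'   with `|rho|` below baseline).
#' @export
replicate_displacement_study <- function(clusters, surfaces,
                                         cfg = displacement_config(),
                                         R = 30, seed = 1, admin = NULL,
                                         by_region = FALSE) {
  stopifnot(R >= 1)
  pa <- perceived_access(clusters, "all")

  correlate_at <- function(x, y, replicate) {
    ma <- lapply(surfaces, extract_at_points, x = x, y = y)
    rows <- list()
    groups <- if (by_region)
      c(list(all = rep(TRUE, nrow(clusters))),
        split_logical(clusters$region_id))
    else list(all = rep(TRUE, nrow(clusters)))
    for (g in names(groups)) {
      keep0 <- groups[[g]]
      for (m in names(ma)) {
        keep <- keep0 & is.finite(pa) & is.finite(ma[[m]])
        if (sum(keep) < 3) next
        s <- spearman_cor(pa[keep], ma[[m]][keep])
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = replicate, method = m, region = g,
          rho_abs = abs(s$rho), sign = sign(s$rho),
          p_value = s$p_value, n = s$n)
      }
    }
    do.call(rbind, rows)
  }

  baseline <- correlate_at(clusters$x, clusters$y, 0L)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed((seed + r * 9973L) %% .Machine$integer.max)
    disp <- displace_points(clusters$x, clusters$y, clusters$urban, cfg, admin)
    reps[[r]] <- correlate_at(disp$x, disp$y, r)
  }
  replicates <- do.call(rbind, reps)

  key <- interaction(replicates$method, replicates$region, drop = TRUE)
  bkey <- interaction(baseline$method, baseline$region, drop = TRUE)
  summ <- lapply(levels(key), function(k) {
    sub <- replicates[key == k, ]
    base <- baseline$rho_abs[bkey == k]
    data.frame(method = sub$method[1], region = sub$region[1],
               baseline_rho_abs = base,
               mean_rho_abs = mean(sub$rho_abs),
               min_rho_abs = min(sub$rho_abs),
               max_rho_abs = max(sub$rho_abs),
               share_attenuated = mean(sub$rho_abs < base),
               n_replicates = nrow(sub))
  })
  list(replicates = replicates, baseline = baseline,
       summary = do.call(rbind, summ))
}

split_logical <- function(f) {
  lv <- sort(unique(f))
  stats::setNames(lapply(lv, function(l) f == l), paste0("region:", lv))
}

#' Displacement distance diagnostics
#'
#' Quality-control summaries of realised displacement distances, per
#' urban/rural class: the empirical maximum and mean, and the
#' Kolmogorov-Smirnov distance between the radial quantile `d / D` and the
#' Uniform(0, 1) distribution it should follow.
#'
#' @param original data.frame with `id`, `x`, `y`, `urban`.
#' @param displaced data.frame with `id`, `x`, `y` and `max_radius` (as
#'   returned by [displace_points()], plus the matching ids).
#' @return data.frame with one row per class: `class`, `n`, `max_distance`,
#'   `mean_distance`, `ks_distance`.
#' @export
displacement_distance_stats <- function(original, displaced) {
  if (!identical(original$id, displaced$id))
    stop("original and displaced tables have mismatched ids", call. = FALSE)
  d <- sqrt((original$x - displaced$x)^2 + (original$y - displaced$y)^2)
  u <- d / displaced$max_radius
  cls <- ifelse(original$urban, "urban", "rural")
  out <- lapply(unique(cls), function(cl) {
    i <- cls == cl
    ui <- u[i][is.finite(u[i])]
    ks <- if (length(ui) >= 2)
      suppressWarnings(stats::ks.test(ui, "punif")$statistic)
    else NA_real_
    data.frame(class = cl, n = sum(i),
               max_distance = max(d[i]), mean_distance = mean(d[i]),
               ks_distance = as.numeric(ks))
  })
  do.call(rbind, out)
}
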