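#' Perceived-accessibility index per cluster
#'
#' The perceived-accessibility (PA) index of a survey cluster is the
#' proportion of its respondents who report distance to the health facility
#' as an obstacle to obtaining medical care. With `subgroup` it is computed
#' within the motorized (household owns a car or motorcycle) or
#' non-motorized respondents only, using the subgroup yes-counts.
#'
#' @param clusters a cluster table: data.frame with columns `n_respondents`,
#'   `n_yes` and, for subgroups, `n_motorized`, `n_yes_motorized`.
#' @param subgroup `"all"`, `"motorized"` or `"non_motorized"`.
#' @return numeric vector of proportions in \[0, 1\]; `NA` (with a warning)
#'   for clusters with zero respondents in the chosen subgroup.
#' @export
perceived_access <- function(clusters,
                             subgroup = c("all", "motorized", "non_motorized")) {
  subgroup <- match.arg(subgroup)
  n <- switch(subgroup,
              all = clusters$n_respondents,
              motorized = clusters$n_motorized,
              non_motorized = clusters$n_respondents - clusters$n_motorized)
  yes <- switch(subgroup,
                all = clusters$n_yes,
                motorized = clusters$n_yes_motorized,
                non_motorized = clusters$n_yes - clusters$n_yes_motorized)
  if (any(yes > n | yes < 0, na.rm = TRUE))
    stop("yes-counts exceed respondent counts", call. = FALSE)
  bad <- !is.na(n) & n == 0
  if (any(bad))
    warning(sum(bad), " cluster(s) with zero respondents excluded (NA)")
  out <- ifelse(n > 0, yes / n, NA_real_)
  as.numeric(out)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of mid-ranks
#' (ties receive average ranks) after pairwise deletion of missing values,
#' with a two-sided p-value from the large-sample t approximation on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n` (pairs used). If either variable
#'   is constant (or fewer than 3 complete pairs remain) `rho` is `NA` and
#'   `undefined` is `TRUE`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Spearman correlation matrix between modelled-accessibility methods
#'
#' Pairwise Spearman correlations between the method columns of a table of
#' extracted modelled-accessibility values (one row per cluster). Reported
#' in absolute value, with the signs retained in the `"sign"` attribute —
#' the kernel-density method is anti-correlated with the distance and
#' travel-time methods by construction.
#'
#' @param ma data.frame of modelled accessibility values; one column per
#'   method (e.g. `ED`, `CD_M`, `CD_W`, `KD`).
#' @return symmetric matrix of `|rho|` with unit diagonal; attributes
#'   `"sign"` (matrix of signs) and `"n"` (pairs per cell).
#' @export
method_correlation_matrix <- function(ma) {
  meth <- names(ma)
  k <- length(meth)
  rho <- diag(1, k); sg <- diag(1, k); nmat <- matrix(NA_integer_, k, k)
  dimnames(rho) <- dimnames(sg) <- dimnames(nmat) <- list(meth, meth)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    s <- spearman_cor(ma[[i]], ma[[j]])
    rho[i, j] <- rho[j, i] <- abs(s$rho)
    sg[i, j] <- sg[j, i] <- sign(s$rho)
    nmat[i, j] <- nmat[j, i] <- s$n
  }
  diag(nmat) <- NROW(ma)
  attr(rho, "sign") <- sg
  attr(rho, "n") <- nmat
  rho
}

#' Stratified PA-MA Spearman correlations
#'
#' Correlates the perceived-accessibility index with each modelled
#' accessibility method, overall and within strata: urban/rural clusters,
#' motorized/non-motorized respondent subgroups (each subgroup's own PA is
#' used, against the cluster-level MA), their crosses, and per region. Strata
#' with fewer than 3 usable clusters are skipped with a message.
#'
#' @param clusters cluster table with columns `urban` (logical),
#'   `region_id`, `n_respondents`, `n_yes`, `n_motorized`, `n_yes_motorized`.
#' @param ma data.frame of modelled accessibility values aligned row-wise
#'   with `clusters` (one column per method).
#' @param strata character vector from `"all"`, `"urban_rural"`,
#'   `"motorized"`, `"urban_rural_x_motorized"`, `"region"`.
#' @param subgroup_pa if `TRUE` (default) the motorized strata use the
#'   subgroup-specific PA; if `FALSE` they reuse the all-respondent PA on
#'   the subgroup-defined cluster subsets (clusters with a majority of
#'   motorized respondents).
#' @return data.frame with one row per (method, stratum): `method`,
#'   `stratum`, `rho_abs`, `sign`, `p_value`, `n`.
#' @export
stratified_pa_ma <- function(clusters, ma,
                             strata = c("all", "urban_rural", "motorized",
                                        "urban_rural_x_motorized", "region"),
                             subgroup_pa = TRUE) {
  strata <- match.arg(strata, several.ok = TRUE)
  pa_all <- perceived_access(clusters, "all")
  specs <- list()
  add <- function(name, pa, keep) specs[[name]] <<- list(pa = pa, keep = keep)
  everything <- rep(TRUE, nrow(clusters))

  if ("all" %in% strata) add("all", pa_all, everything)
  if ("urban_rural" %in% strata) {
    add("urban", pa_all, clusters$urban)
    add("rural", pa_all, !clusters$urban)
  }
  motor_pa <- function(sub) {
    if (subgroup_pa) suppressWarnings(perceived_access(clusters, sub)) else pa_all
  }
  motor_keep <- function(sub) {
    if (subgroup_pa) {
      if (sub == "motorized") clusters$n_motorized > 0
      else clusters$n_respondents - clusters$n_motorized > 0
    } else {
      maj <- clusters$n_motorized / clusters$n_respondents >= 0.5
      if (sub == "motorized") maj else !maj
    }
  }
  if ("motorized" %in% strata) {
    add("motorized", motor_pa("motorized"), motor_keep("motorized"))
    add("non_motorized", motor_pa("non_motorized"), motor_keep("non_motorized"))
  }
  if ("urban_rural_x_motorized" %in% strata) {
    for (ur in c(TRUE, FALSE)) for (sub in c("motorized", "non_motorized")) {
      nm <- paste0(if (ur) "urban" else "rural", "_", sub)
      add(nm, motor_pa(sub),
          motor_keep(sub) & (if (ur) clusters$urban else !clusters$urban))
    }
  }
  if ("region" %in% strata) {
    for (rid in sort(unique(clusters$region_id)))
      add(paste0("region:", rid), pa_all, clusters$region_id == rid)
  }

  rows <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    for (m in names(ma)) {
      keep <- sp$keep & is.finite(sp$pa) & is.finite(ma[[m]])
      if (sum(keep) < 3) {
        message("stratum '", nm, "' skipped for ", m,
                " (fewer than 3 clusters)")
        next
      }
      s <- spearman_cor(sp$pa[keep], ma[[m]][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, stratum = nm,
        rho_abs = abs(s$rho), sign = sign(s$rho),
        p_value = s$p_value, n = s$n)
    }
  }
  do.call(rbind, rows)
}

#' Locally weighted smoothing curve
#'
#' Local linear regression with tricube weights (LOESS, degree 1), evaluated
#' on an even grid over the x-range. For visualising the shape of the PA-MA
#' relationship only; not used in any statistic.
#'
#' @param x,y numeric vectors (at least 10 finite pairs).
#' @param span smoothing span (fraction of points per local fit).
#' @param n_out number of grid points.
#' @return data.frame with columns `x`, `y`.
#' @export
loess_curve <- function(x, y, span = 0.75, n_out = 100) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("at least 10 finite (x, y) pairs required", call. = FALSE)
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  xg <- seq(min(x), max(x), length.out = n_out)
  data.frame(x = xg, y = as.numeric(stats::predict(fit, newdata = data.frame(x = xg))))
}

#' Population shares by accessibility class
#'
#' Splits the total population into accessibility bands. Classes are
#' right-closed: `(-Inf, b1], (b1, b2], ..., (bk, Inf)`, so "less than 5 km"
#' corresponds to values `<= 5000` at cell resolution. Cells with `NA`
#' accessibility (nodata, e.g. outside the resampled source extent) are
#' reported as a separate `unclassified` share; unreachable (`Inf`) cells
#' fall in the open top class. Not defined for the kernel-density method,
#' whose dimensionless values have no distance interpretation.
#'
#' @param surface an [access_surface()] (method ED, CD_M or CD_W) on the
#'   same geometry as `population` (use [resample_to()] first otherwise).
#' @param population a [raster_grid()] of population counts.
#' @param breaks strictly increasing positive class boundaries, in the
#'   surface's units (meters for ED, minutes for CD).
#' @return data.frame with `class` labels, `share` (of total population) and
#'   `population`; shares sum to 1 over classes plus `unclassified`.
#' @export
population_by_class <- function(surface, population, breaks) {
  stopifnot(inherits(surface, "access_surface"))
  if (surface$method == "KD")
    stop("population-by-class is not defined for the KD method", call. = FALSE)
  if (any(diff(breaks) <= 0) || breaks[1] <= 0)
    stop("breaks must be strictly increasing and positive", call. = FALSE)
  if (!identical(dim(surface$grid$values), dim(population$values)))
    stop("surface and population grids have different shapes; resample first",
         call. = FALSE)
  acc <- as.vector(surface$grid$values)
  pop <- as.vector(population$values)
  pop[is.na(pop)] <- 0
  total <- sum(pop)
  if (total <= 0) stop("population grid is empty (zero total)", call. = FALSE)
  edges <- c(-Inf, breaks, Inf)
  labels <- c(paste0("<=", breaks),
              paste0(">", breaks[length(breaks)]))
  cls <- cut(acc, breaks = edges, labels = labels, right = TRUE)
  pops <- vapply(labels, function(l) sum(pop[!is.na(cls) & cls == l]),
                 numeric(1))
  pops <- c(pops, unclassified = sum(pop[is.na(acc)]))
  data.frame(class = names(pops), population = as.numeric(pops),
             share = as.numeric(pops) / total, row.names = NULL)
}
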