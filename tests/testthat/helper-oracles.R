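# Independent oracles used to check the package's surfaces and statistics.
# These are deliberately naive re-implementations (brute force, explicit
# loops) that share no code with the package internals.

# naive multi-source Dijkstra on an explicit edge list built cell by cell;
# friction matrix f (min/m), projected grid with square cells of size cs
brute_dijkstra <- function(f, cs, source_cells, connectivity = 8) {
  nr <- nrow(f); nc <- ncol(f)
  id <- function(r, c) (r - 1) * nc + c
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  if (connectivity == 16)
    offs <- rbind(offs,
                  c(1, 2), c(1, -2), c(-1, 2), c(-1, -2),
                  c(2, 1), c(2, -1), c(-2, 1), c(-2, -1))
  n <- nr * nc
  dist <- rep(Inf, n)
  for (s in seq_len(nrow(source_cells)))
    dist[id(source_cells[s, 1], source_cells[s, 2])] <- 0
  visited <- rep(FALSE, n)
  repeat {
    masked <- dist
    masked[visited] <- Inf
    u <- which.min(masked)
    if (!is.finite(masked[u])) break
    visited[u] <- TRUE
    r <- (u - 1) %/% nc + 1; c <- (u - 1) %% nc + 1
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- cs * sqrt(offs[k, 1]^2 + offs[k, 2]^2) * (f[r, c] + f[r2, c2]) / 2
      if (!is.finite(w)) next
      v <- id(r2, c2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc, byrow = TRUE)
}

# per-cell min distance over facilities, explicit double loop
brute_euclidean <- function(grid, fac) {
  out <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (r in seq_len(grid$nrows)) for (c in seq_len(grid$ncols)) {
    cx <- grid$x_origin + (c - 0.5) * grid$cell_size
    cy <- grid$y_origin - (r - 0.5) * grid$cell_size
    best <- Inf
    for (i in seq_len(nrow(fac))) {
      d <- if (grid$crs_kind == "projected_m") {
        sqrt((cx - fac$x[i])^2 + (cy - fac$y[i])^2)
      } else {
        hav_oracle(cx, cy, fac$x[i], fac$y[i])
      }
      best <- min(best, d)
    }
    out[r, c] <- best
  }
  out
}

# spherical law of cosines (an independent great-circle formula)
slc_oracle <- function(lon1, lat1, lon2, lat2, R = 6371009) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  R * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# haversine written out longhand (used inside the brute ED oracle)
hav_oracle <- function(lon1, lat1, lon2, lat2, R = 6371009) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- p2 - p1; dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# mid-ranks by counting, then the Pearson product-moment formula by hand
brute_spearman <- function(x, y) {
  midrank <- function(v)
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# small random friction landscape with optional impassable cells
random_friction <- function(nr, nc, cs = 1000, p_barrier = 0.1, seed = 1) {
  set.seed(seed)
  f <- matrix(exp(stats::runif(nr * nc, log(0.002), log(0.05))), nr, nc)
  if (p_barrier > 0)
    f[stats::runif(nr * nc) < p_barrier] <- Inf
  friction_surface(raster_grid(f, 0, nr * cs, cs, "projected_m"), "walking")
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  both_inf <- is.infinite(object) & is.infinite(expected)
  rel <- abs(object - expected) / pmax(abs(expected), 1e-12)
  rel[both_inf] <- 0
  expect_lt(max(rel, na.rm = TRUE), tol)
}
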