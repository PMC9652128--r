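#' Friction surface
#'
#' Wraps a [raster_grid()] whose cells hold traversal time per unit distance
#' (minutes per meter). A uniform value of 0.012 min/m corresponds to walking
#' at 5 km/h; 0.0012 min/m to driving at 50 km/h. Impassable cells are `Inf`
#' (or `NA` on disk).
#'
#' @param grid a [raster_grid()] of friction values (min/m).
#' @param mode `"walking"` or `"motorized"`; a label carried to outputs.
#' @return a `friction_surface`.
#' @export
friction_surface <- function(grid, mode = c("walking", "motorized")) {
  mode <- match.arg(mode)
  validate_raster_grid(grid)
  v <- grid$values
  if (any(v[is.finite(v)] <= 0))
    stop("friction values must be positive (impassable cells are Inf/NA)",
         call. = FALSE)
  structure(list(grid = grid, mode = mode), class = "friction_surface")
}

#' Gaussian kernel configuration
#'
#' Parameters of the facility kernel-density score: contributions follow an
#' unnormalized Gaussian `exp(-d^2 / (2 sigma^2))` in distance `d` and are
#' truncated to exactly zero beyond `threshold`.
#'
#' @param threshold truncation distance in meters (default 15,000 m = 15 km).
#' @param sigma Gaussian scale in meters; defaults to `threshold / 3`.
#' @return a `kernel_config`.
#' @export
kernel_config <- function(threshold = 15000, sigma = threshold / 3) {
  stopifnot(threshold > 0, sigma > 0)
  structure(list(threshold = threshold, sigma = sigma),
            class = "kernel_config")
}

#' Accessibility surface
#'
#' A [raster_grid()] tagged with the modelling method that produced it and
#' its units. Methods: `ED` (Euclidean distance to the nearest facility,
#' meters), `CD_M`/`CD_W` (motorized/walking cost-distance travel time,
#' minutes), `KD` (truncated Gaussian kernel density of facilities,
#' dimensionless; higher = better access, the opposite sign convention to
#' the other three).
#'
#' @param grid a [raster_grid()].
#' @param method one of `"ED"`, `"CD_M"`, `"CD_W"`, `"KD"`.
#' @param units one of `"meters"`, `"minutes"`, `"dimensionless"`.
#' @return an `access_surface`.
#' @export
access_surface <- function(grid, method = c("ED", "CD_M", "CD_W", "KD"),
                           units = c("meters", "minutes", "dimensionless")) {
  method <- match.arg(method)
  units <- match.arg(units)
  validate_raster_grid(grid)
  structure(list(grid = grid, method = method, units = units),
            class = "access_surface")
}

#' @export
print.access_surface <- function(x, ...) {
  cat(sprintf("<access_surface> method %s (%s)\n", x$method, x$units))
  print(x$grid)
  invisible(x)
}

# all cell centers of a grid, as vectors recycled in column-major cell order
grid_centers <- function(grid) {
  rows <- rep(seq_len(grid$nrows), times = grid$ncols)
  cols <- rep(seq_len(grid$ncols), each = grid$nrows)
  list(rows = rows, cols = cols,
       x = grid$x_origin + (cols - 0.5) * grid$cell_size,
       y = grid$y_origin - (rows - 0.5) * grid$cell_size)
}

#' Euclidean-distance accessibility surface (ED)
#'
#' Each cell holds the distance in meters from its center to the closest
#' facility point. Facilities are used at their exact coordinates (not
#' snapped to cells). Geographic grids use haversine distances.
#'
#' @param template a [raster_grid()] defining extent, resolution and CRS.
#' @param facilities a [facility_set()]; must be non-empty.
#' @return an [access_surface()] with method `"ED"` and units meters.
#' @export
euclidean_surface <- function(template, facilities) {
  if (NROW(facilities) == 0) stop("facility set is empty", call. = FALSE)
  ctr <- grid_centers(template)
  best <- rep(Inf, length(ctr$x))
  for (i in seq_len(NROW(facilities))) {
    d <- point_distance(template, ctr$x, ctr$y,
                        facilities$x[i], facilities$y[i])
    best <- pmin(best, d)
  }
  m <- matrix(best, nrow = template$nrows, ncol = template$ncols)
  access_surface(raster_grid(m, template$x_origin, template$y_origin,
                             template$cell_size, template$crs_kind,
                             template$nodata),
                 method = "ED", units = "meters")
}

# neighbor offsets (dr, dc), one direction per undirected edge family
connectivity_offsets <- function(connectivity) {
  base <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (connectivity == 8) return(base)
  rbind(base, c(1, 2), c(2, 1), c(2, -1), c(1, -2))
}

#' Cost-distance accessibility surface (CD-M / CD-W)
#'
#' Multi-source accumulated least travel time, in minutes, from the set of
#' facility cells over the raster graph. Adjacent cells `a`, `b` are joined
#' by an edge of weight `dist(a, b) * (f_a + f_b) / 2`, where `dist` is the
#' inter-center distance in meters and `f` the friction in min/m. Facility
#' cells start at 0; cells unreachable from every facility (e.g. behind
#' impassable barriers) are `Inf`. The result equals a single Dijkstra run
#' with all facility cells initialized at zero cost.
#'
#' Facilities are snapped to their containing cell; facilities outside the
#' grid are dropped with a warning (all outside is an error). Multiple
#' facilities in one cell collapse to a single source.
#'
#' @param friction a [friction_surface()].
#' @param facilities a [facility_set()].
#' @param connectivity 8 (queen moves) or 16 (queen + knight moves; smaller
#'   raster-metric elongation).
#' @return an [access_surface()] with method `"CD_M"` or `"CD_W"` (from the
#'   friction mode) and units minutes.
#' @export
cost_distance_surface <- function(friction, facilities, connectivity = 8) {
  stopifnot(inherits(friction, "friction_surface"))
  if (!connectivity %in% c(8, 16))
    stop("connectivity must be 8 or 16", call. = FALSE)
  if (NROW(facilities) == 0) stop("facility set is empty", call. = FALSE)
  grid <- friction$grid
  cells <- point_to_cell(grid, facilities$x, facilities$y)
  if (any(!cells$inside)) {
    warning(sum(!cells$inside), " facility point(s) outside the grid dropped")
    cells <- cells[cells$inside, , drop = FALSE]
  }
  if (nrow(cells) == 0) stop("all facilities fall outside the grid", call. = FALSE)

  nr <- grid$nrows; nc <- grid$ncols
  f <- grid$values
  f[is.na(f)] <- Inf
  cell_id <- function(r, c) (c - 1L) * nr + r   # column-major, matches matrix indexing

  offs <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    rr <- rep(r1, times = length(c1)); cc <- rep(c1, each = length(r1))
    a <- cell_id(rr, cc); b <- cell_id(rr + dr, cc + dc)
    ww <- cell_center_distance(grid, cbind(rr, cc), cbind(rr + dr, cc + dc)) *
      (f[a] + f[b]) / 2
    keep <- is.finite(ww)
    from <- c(from, a[keep]); to <- c(to, b[keep]); w <- c(w, ww[keep])
  }

  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  src <- unique(cell_id(cells$row, cells$col))
  dmat <- igraph::distances(g, v = src, weights = igraph::E(g)$weight,
                            algorithm = "dijkstra")
  acc <- apply(dmat, 2, min)
  m <- matrix(acc, nrow = nr, ncol = nc)   # column-major matches cell_id
  method <- if (friction$mode == "motorized") "CD_M" else "CD_W"
  access_surface(raster_grid(m, grid$x_origin, grid$y_origin, grid$cell_size,
                             grid$crs_kind, grid$nodata),
                 method = method, units = "minutes")
}

#' Kernel-density accessibility surface (KD)
#'
#' Each cell holds the sum over facilities of a truncated Gaussian kernel of
#' the distance between the cell center and the facility point:
#' `k(d) = exp(-d^2 / (2 sigma^2))` for `d <= threshold`, and exactly 0
#' beyond. A lone facility at a cell center contributes 1 there. Values grow
#' with accessibility — the opposite sign convention to ED/CD.
#'
#' @param template a [raster_grid()].
#' @param facilities a [facility_set()]; coincident facilities each count.
#' @param cfg a [kernel_config()].
#' @return an [access_surface()] with method `"KD"`, dimensionless.
#' @export
kernel_density_surface <- function(template, facilities,
                                   cfg = kernel_config()) {
  if (NROW(facilities) == 0) stop("facility set is empty", call. = FALSE)
  stopifnot(inherits(cfg, "kernel_config"))
  ctr <- grid_centers(template)
  acc <- numeric(length(ctr$x))
  for (i in seq_len(NROW(facilities))) {
    d <- point_distance(template, ctr$x, ctr$y,
                        facilities$x[i], facilities$y[i])
    k <- exp(-d^2 / (2 * cfg$sigma^2))
    k[d > cfg$threshold] <- 0
    acc <- acc + k
  }
  m <- matrix(acc, nrow = template$nrows, ncol = template$ncols)
  access_surface(raster_grid(m, template$x_origin, template$y_origin,
                             template$cell_size, template$crs_kind,
                             template$nodata),
                 method = "KD", units = "dimensionless")
}

#' Resample an accessibility surface onto a template grid
#'
#' Nearest-neighbor lookup: each template cell takes the value of the source
#' cell containing the template cell's center. Template cells whose centers
#' fall outside the source extent become `NA` (with a warning if all do).
#'
#' @param surface an [access_surface()].
#' @param template a [raster_grid()] defining the output geometry.
#' @return an [access_surface()] on the template geometry.
#' @export
resample_to <- function(surface, template) {
  stopifnot(inherits(surface, "access_surface"))
  src <- surface$grid
  ctr <- grid_centers(template)
  cells <- point_to_cell(src, ctr$x, ctr$y)
  vals <- rep(NA_real_, length(ctr$x))
  ok <- cells$inside
  vals[ok] <- src$values[cbind(cells$row[ok], cells$col[ok])]
  if (length(ok) && !any(ok))
    warning("template lies entirely outside the source surface")
  m <- matrix(vals, nrow = template$nrows, ncol = template$ncols)
  access_surface(raster_grid(m, template$x_origin, template$y_origin,
                             template$cell_size, template$crs_kind,
                             template$nodata),
                 method = surface$method, units = surface$units)
}

#' Extract surface values at points
#'
#' Returns the value of the cell containing each point; points outside the
#' grid or on nodata cells give `NA`.
#'
#' @param surface an [access_surface()] (or a bare [raster_grid()]).
#' @param x,y point coordinates.
#' @return numeric vector of values.
#' @export
extract_at_points <- function(surface, x, y) {
  grid <- if (inherits(surface, "access_surface")) surface$grid else surface
  cells <- point_to_cell(grid, x, y)
  vals <- rep(NA_real_, length(x))
  ok <- cells$inside
  vals[ok] <- grid$values[cbind(cells$row[ok], cells$col[ok])]
  vals
}
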