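#' Georeferenced raster grid
#'
#' Construct a `raster_grid`, the basic gridded data container used throughout
#' the package for friction surfaces, population counts and accessibility
#' values. The grid stores a numeric matrix in map orientation (row 1 is the
#' northernmost row) together with the coordinates of the *outer* corner of
#' the top-left cell, the (square) cell size, and the kind of coordinate
#' reference system.
#'
#' The cell-center convention used by every point/cell conversion in the
#' package is: the center of cell `(r, c)` (1-based) lies at
#' `x = x_origin + (c - 0.5) * cell_size` and
#' `y = y_origin - (r - 0.5) * cell_size`.
#'
#' @param values numeric matrix, row 1 = northernmost row. `NA` marks nodata;
#'   `Inf` marks unreachable/impassable cells (written out as nodata).
#' @param x_origin,y_origin coordinates of the outer corner of the top-left
#'   cell, in map units (meters for projected grids, degrees for geographic).
#' @param cell_size positive cell edge length in map units (square cells).
#' @param crs_kind `"projected_m"` (planar meters) or `"geographic_deg"`
#'   (longitude/latitude degrees; distances use the haversine formula).
#' @param nodata sentinel value used on disk for missing cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, x_origin, y_origin, cell_size,
                        crs_kind = c("projected_m", "geographic_deg"),
                        nodata = -9999) {
  crs_kind <- match.arg(crs_kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  g <- structure(
    list(values = values, nrows = nrow(values), ncols = ncol(values),
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
         crs_kind = crs_kind),
    class = "raster_grid")
  validate_raster_grid(g)
}

validate_raster_grid <- function(g) {
  stopifnot(inherits(g, "raster_grid"))
  if (!identical(dim(g$values), c(g$nrows, g$ncols)))
    stop("values shape does not match (nrows, ncols)", call. = FALSE)
  if (g$cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g, %s\n",
              x$nrows, x$ncols, x$cell_size, x$crs_kind))
  cat(sprintf("  origin (top-left outer corner): (%g, %g)\n",
              x$x_origin, x$y_origin))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  finite values: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' Cell centers of a raster grid
#'
#' @param grid a [raster_grid()].
#' @param row,col 1-based row/column indices (vectors of equal length).
#' @return two-column matrix of (x, y) map coordinates of the cell centers.
#' @export
cell_center <- function(grid, row, col) {
  cbind(x = grid$x_origin + (col - 0.5) * grid$cell_size,
        y = grid$y_origin - (row - 0.5) * grid$cell_size)
}

#' Locate the cells containing points
#'
#' Cells are half-open in both axes: a cell owns the interval
#' `[left, right)` in x and `(bottom, top]` in y, so a point exactly on an
#' interior boundary belongs to the cell with the larger row/column index.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates (equal-length vectors).
#' @return data.frame with 1-based `row`, `col` (NA when outside) and a
#'   logical `inside` flag.
#' @export
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$x_origin) / grid$cell_size) + 1
  row <- floor((grid$y_origin - y) / grid$cell_size) + 1
  # y exactly on the top edge of the grid belongs to row 1 ((bottom, top])
  row[(grid$y_origin - y) == 0] <- 1
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= grid$nrows & col >= 1 & col <= grid$ncols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Distance between two cell centers
#'
#' Planar Euclidean distance for projected grids; haversine great-circle
#' distance (Earth radius 6,371,009 m) for geographic grids. Returns meters
#' in both cases (projected map units are assumed to be meters).
#'
#' @param grid a [raster_grid()].
#' @param cellA,cellB length-2 vectors `c(row, col)` or two-column matrices.
#' @return distance(s) in meters.
#' @export
cell_center_distance <- function(grid, cellA, cellB) {
  if (!is.matrix(cellA)) cellA <- matrix(cellA, ncol = 2)
  if (!is.matrix(cellB)) cellB <- matrix(cellB, ncol = 2)
  a <- cell_center(grid, cellA[, 1], cellA[, 2])
  b <- cell_center(grid, cellB[, 1], cellB[, 2])
  unname(point_distance(grid, a[, 1], a[, 2], b[, 1], b[, 2]))
}

# distance between arbitrary coordinate pairs under the grid's CRS (meters)
point_distance <- function(grid, x1, y1, x2, y2) {
  if (grid$crs_kind == "projected_m") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  } else {
    n <- max(length(x1), length(x2))
    p1 <- cbind(rep_len(x1, n), rep_len(y1, n))
    p2 <- cbind(rep_len(x2, n), rep_len(y2, n))
    geosphere::distHaversine(p1, p2, r = 6371009)
  }
}

#' Read a raster grid from disk
#'
#' Reads the ESRI ASCII grid format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by north-to-south rows). Nodata
#' cells become `NA`. GeoTIFF is not supported by this build and raises an
#' error.
#'
#' @param path file path.
#' @param format `"esri_ascii"` (default) or `"geotiff"` (unsupported).
#' @param crs_kind CRS kind to tag the grid with (the ASCII format does not
#'   record one).
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, format = c("esri_ascii", "geotiff"),
                        crs_kind = c("projected_m", "geographic_deg")) {
  format <- match.arg(format)
  crs_kind <- match.arg(crs_kind)
  if (format == "geotiff")
    stop("GeoTIFF is not supported by this build; use format = \"esri_ascii\"",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  keywords <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% keywords) break
    hdr[[key]] <- as.numeric(parts[2])
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(required %in% names(hdr)))
    stop("not a valid ESRI ASCII grid header: ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- length(hdr)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("cell count does not match header in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m,
              x_origin = hdr$xllcorner,
              y_origin = hdr$yllcorner + nr * hdr$cellsize,
              cell_size = hdr$cellsize, crs_kind = crs_kind, nodata = nodata)
}

#' Write a raster grid to disk
#'
#' Writes the ESRI ASCII grid format. `NA` and non-finite cells (including
#' the internal `Inf` unreachable sentinel) are written as the nodata value.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param format `"esri_ascii"` (default) or `"geotiff"` (unsupported).
#' @export
write_raster <- function(grid, path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF is not supported by this build; use format = \"esri_ascii\"",
         call. = FALSE)
  validate_raster_grid(grid)
  m <- grid$values
  m[!is.finite(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$x_origin),
    sprintf("yllcorner %.10g", grid$y_origin - grid$nrows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(NULL)
}
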