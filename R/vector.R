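#' Health-facility point set
#'
#' @param x,y facility coordinates in the grid CRS.
#' @param id optional facility identifiers (defaults to 1..n).
#' @return a `facility_set`: a data.frame with columns `id`, `x`, `y`.
#' @export
facility_set <- function(x, y, id = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (is.null(id)) id <- seq_along(x)
  structure(data.frame(id = id, x = as.numeric(x), y = as.numeric(y)),
            class = c("facility_set", "data.frame"))
}

#' Read facilities from a CSV file (columns id, x, y)
#' @param path file path.
#' @return a [facility_set()].
#' @export
read_facilities_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("facility CSV must have columns x and y", call. = FALSE)
  facility_set(d$x, d$y, id = if ("id" %in% names(d)) d$id else NULL)
}

#' Write facilities to CSV
#' @param facilities a [facility_set()].
#' @param path output path.
#' @export
write_facilities_csv <- function(facilities, path) {
  utils::write.csv(as.data.frame(facilities), path, row.names = FALSE)
  invisible(NULL)
}

#' Read facilities from a GeoJSON FeatureCollection of Points
#' @param path file path.
#' @return a [facility_set()].
#' @export
read_facilities_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates)[1:2],
                 numeric(2)))
  ids <- vapply(feats, function(f) {
    if (!is.null(f$properties$id)) as.character(f$properties$id) else NA_character_
  }, character(1))
  if (anyNA(ids)) ids <- seq_len(nrow(xy))
  facility_set(xy[, 1], xy[, 2], id = ids)
}

#' Write facilities to GeoJSON
#' @param facilities a [facility_set()].
#' @param path output path.
#' @export
write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) {
    list(type = "Feature",
         properties = list(id = facilities$id[i]),
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[i], facilities$y[i])))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Administrative polygons
#'
#' A light container for simple polygons (optionally with holes) in the grid
#' CRS, used to constrain the geomasking displacement. Each polygon is a list
#' of rings; the first ring is the outer boundary, subsequent rings are holes.
#' Membership uses the even-odd rule.
#'
#' @param rings list of polygons; each polygon is a list of two-column
#'   matrices of ring vertices (closed or open; closure is implicit).
#' @param id polygon identifiers.
#' @return an `admin_polygons` object.
#' @export
admin_polygons <- function(rings, id = NULL) {
  if (is.null(id)) id <- seq_along(rings)
  rings <- lapply(rings, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      r
    })
  })
  structure(list(rings = rings, id = id), class = "admin_polygons")
}

# single-polygon boundary matrix with NA rows separating rings (mgcv::in.out)
poly_boundary <- function(poly) {
  parts <- lapply(poly, function(r) rbind(r, r[1, , drop = FALSE]))
  out <- parts[[1]]
  for (k in seq_along(parts)[-1])
    out <- rbind(out, matrix(NA_real_, 1, 2), parts[[k]])
  out
}

#' Test point-in-polygon membership
#'
#' @param admin an [admin_polygons()] object.
#' @param x,y point coordinates.
#' @return integer vector: for each point, the id of the FIRST polygon (in
#'   file order) containing it, or `NA` if none does.
#' @export
assign_polygon <- function(admin, x, y) {
  pts <- cbind(as.numeric(x), as.numeric(y))
  out <- rep(NA, nrow(pts))
  storage.mode(out) <- storage.mode(admin$id)
  for (i in seq_along(admin$rings)) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    inside <- mgcv::in.out(poly_boundary(admin$rings[[i]]),
                           pts[todo, , drop = FALSE])
    out[todo[inside]] <- admin$id[i]
  }
  out
}

#' Read admin polygons from a GeoJSON FeatureCollection of Polygons
#' @param path file path.
#' @return an [admin_polygons()] object.
#' @export
read_admin_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  rings <- lapply(feats, function(f) {
    stopifnot(f$geometry$type == "Polygon")
    lapply(f$geometry$coordinates, function(ring) {
      t(vapply(ring, function(pt) unlist(pt)[1:2], numeric(2)))
    })
  })
  ids <- vapply(feats, function(f) {
    if (!is.null(f$properties$id)) as.character(f$properties$id) else NA_character_
  }, character(1))
  if (anyNA(ids)) ids <- seq_along(rings)
  admin_polygons(rings, id = ids)
}

#' Write admin polygons to GeoJSON
#' @param admin an [admin_polygons()] object.
#' @param path output path.
#' @export
write_admin_geojson <- function(admin, path) {
  feats <- lapply(seq_along(admin$rings), function(i) {
    coords <- lapply(admin$rings[[i]], function(r) {
      r <- rbind(r, r[1, , drop = FALSE])   # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    })
    list(type = "Feature",
         properties = list(id = admin$id[i]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
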