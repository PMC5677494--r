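## Small geometry helpers shared by the effort ledger, prediction grids
## and the synthetic generator.

#' Test whether points fall inside a polygon
#'
#' Thin wrapper around [mgcv::in.out()]. The polygon is a two-column
#' matrix of vertices (closed or open ring, either orientation).
#'
#' @param px,py point coordinates (same units as the polygon).
#' @param poly two-column matrix or data.frame of polygon vertices.
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly[, 1:2])
  storage.mode(poly) <- "double"
  ## in.out wants an open ring terminated by NA-free coords; close it
  if (!all(poly[1, ] == poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, cbind(as.numeric(px), as.numeric(py)))
}

#' Read a polygon from a GeoJSON file
#'
#' Reads the first Polygon geometry (outer ring only) from a GeoJSON
#' Feature, FeatureCollection or bare geometry. Coordinates are WGS84
#' lon/lat as mandated by the GeoJSON specification.
#'
#' @param path path to a `.geojson` file.
#' @return two-column matrix with columns `lon`, `lat`.
#' @export
read_footprint <- function(path) {
  g <- jsonlite::read_json(path)
  geom <- if (!is.null(g$type) && g$type == "FeatureCollection")
    g$features[[1]]$geometry
  else if (!is.null(g$type) && g$type == "Feature") g$geometry
  else g
  if (is.null(geom$type) || geom$type != "Polygon")
    stop("expected a Polygon geometry in ", path)
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("lon", "lat")
  m
}

#' Write a polygon to a GeoJSON file
#'
#' @param poly two-column matrix of `lon`, `lat` vertices.
#' @param path output path.
#' @param properties named list of feature properties.
#' @return `path`, invisibly.
#' @export
write_footprint <- function(poly, path, properties = list()) {
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  ring <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
  feat <- list(
    type = "Feature",
    properties = properties,
    geometry = list(type = "Polygon", coordinates = list(ring))
  )
  fc <- list(type = "FeatureCollection", features = list(feat))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## convex hull of points as a closed polygon matrix
.convex_hull <- function(x, y) {
  i <- grDevices::chull(x, y)
  cbind(x = x[i], y = y[i])
}
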