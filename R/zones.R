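#' Zone systems
#'
#' A `zone_system` is the package's stand-in for a census zone geography
#' (MSOA-like polygons): a set of uniquely identified, interior-disjoint
#' WGS84 polygons plus their bounding box. Grid systems built by
#' [generate_zones()] are the default test-bed; arbitrary polygon systems can
#' be read from GeoJSON with [read_zones_geojson()].
#'
#' @param zone_id character vector of unique zone identifiers.
#' @param rings list of closed rings, one per zone: numeric matrices with
#'   columns `lon, lat`, first row equal to last row.
#' @return an object of class `zone_system`: a list with elements `zones`
#'   (a tibble with columns `zone_id`, `ring`) and `bbox`
#'   (`c(lon_min, lat_min, lon_max, lat_max)`).
#' @export
zone_system <- function(zone_id, rings) {
  if (length(zone_id) != length(rings)) {
    stop_mobflow("zone_id and rings must have the same length")
  }
  if (anyDuplicated(zone_id)) stop_mobflow("zone ids must be unique")
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 4) {
      stop_mobflow("each ring must be a matrix with columns lon,lat and >= 4 rows")
    }
    if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE))) {
      stop_mobflow("rings must be closed (first vertex == last vertex)")
    }
  }
  lons <- unlist(lapply(rings, function(r) r[, 1]))
  lats <- unlist(lapply(rings, function(r) r[, 2]))
  structure(
    list(
      zones = tibble::tibble(zone_id = as.character(zone_id), ring = rings),
      bbox = c(
        lon_min = min(lons), lat_min = min(lats),
        lon_max = max(lons), lat_max = max(lats)
      )
    ),
    class = "zone_system"
  )
}

#' @export
print.zone_system <- function(x, ...) {
  cat(
    "<zone_system> ", nrow(x$zones), " zones; bbox [",
    sprintf("%.4f, %.4f, %.4f, %.4f", x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]),
    "] (lon_min, lat_min, lon_max, lat_max)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of zones in a zone system
#' @param zones a [zone_system()].
#' @return integer count.
#' @export
n_zones <- function(zones) nrow(zones$zones)

#' Zone ids of a zone system
#' @param zones a [zone_system()].
#' @return character vector.
#' @export
zone_ids <- function(zones) zones$zones$zone_id

#' Generate a rectangular grid of square zones
#'
#' Builds a `rows` x `cols` tessellation of axis-aligned square zones as a
#' stand-in for real census-zone polygons; the flow and spatial statistics in
#' this package depend only on contiguity topology and flows, not on real
#' zone shapes. Zone `Z_r_c` occupies row `r` (south to north) and column `c`
#' (west to east), each cell `cell_deg` degrees on a side.
#'
#' @param rows,cols positive integer grid dimensions.
#' @param cell_deg positive cell edge length, in degrees (applied to both
#'   latitude and longitude).
#' @param origin numeric `c(lat, lon)` of the grid's south-west corner.
#' @return a [zone_system()] with `rows * cols` zones tiling the rectangle
#'   from `origin` to `origin + c(rows, cols) * cell_deg`.
#' @examples
#' z <- generate_zones(3, 3, 0.01, origin = c(51.5, -0.1))
#' n_zones(z)
#' @export
generate_zones <- function(rows, cols, cell_deg, origin = c(51.5, -0.1)) {
  if (rows < 1 || cols < 1) stop_mobflow("rows and cols must be >= 1")
  if (cell_deg <= 0) stop_mobflow("cell_deg must be positive")
  lat0 <- origin[1]
  lon0 <- origin[2]
  ids <- character(rows * cols)
  rings <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      ids[k] <- sprintf("Z_%d_%d", r, c)
      x0 <- lon0 + (c - 1) * cell_deg
      y0 <- lat0 + (r - 1) * cell_deg
      x1 <- x0 + cell_deg
      y1 <- y0 + cell_deg
      rings[[k]] <- cbind(
        lon = c(x0, x1, x1, x0, x0),
        lat = c(y0, y0, y1, y1, y0)
      )
    }
  }
  zone_system(ids, rings)
}

#' Zone centroids
#'
#' Planar centroid of each zone's ring (mean of distinct vertices for convex
#' grid cells; exact for rectangles).
#'
#' @param zones a [zone_system()].
#' @return tibble with columns `zone_id`, `lat`, `lon`.
#' @export
zone_centroids <- function(zones) {
  cent <- t(vapply(zones$zones$ring, function(r) {
    v <- r[-nrow(r), , drop = FALSE]
    c(mean(v[, 1]), mean(v[, 2]))
  }, numeric(2)))
  tibble::tibble(zone_id = zones$zones$zone_id, lat = cent[, 2], lon = cent[, 1])
}

# Boundary-inclusive point-in-ring test (even-odd ray casting). Points lying
# on an edge or vertex count as inside, so zone assignment is deterministic;
# a point on a shared boundary goes to the first zone in id order.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  on_bd <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_bd <- on_bd | (abs(cross) < 1e-12 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_bd
}

#' Locate points in a zone system
#'
#' Point-in-polygon assignment of coordinates to zones. Boundary points count
#' as inside; a point on a shared boundary is assigned to the first matching
#' zone in id order.
#'
#' @param lat,lon numeric coordinate vectors of equal length.
#' @param zones a [zone_system()].
#' @return character vector of zone ids, `NA` where a point falls in no zone.
#' @export
locate_zones <- function(lat, lon, zones) {
  out <- rep(NA_character_, length(lat))
  todo <- rep(TRUE, length(lat))
  for (k in seq_len(nrow(zones$zones))) {
    ring <- zones$zones$ring[[k]]
    cand <- which(
      todo &
        lon >= min(ring[, 1]) - 1e-12 & lon <= max(ring[, 1]) + 1e-12 &
        lat >= min(ring[, 2]) - 1e-12 & lat <= max(ring[, 2]) + 1e-12
    )
    if (!length(cand)) next
    hit <- point_in_ring(lon[cand], lat[cand], ring)
    out[cand[hit]] <- zones$zones$zone_id[k]
    todo[cand[hit]] <- FALSE
  }
  out
}

#' Write a zone system as GeoJSON
#'
#' @param zones a [zone_system()].
#' @param path output file path.
#' @param properties optional data frame of extra per-zone properties joined
#'   by `zone_id` (e.g. attractiveness shares or community labels).
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(zones$zones)), function(k) {
    props <- list(zone_id = zones$zones$zone_id[k])
    if (!is.null(properties)) {
      row <- properties[properties$zone_id == zones$zones$zone_id[k], , drop = FALSE]
      if (nrow(row) == 1) {
        for (nm in setdiff(names(row), "zone_id")) props[[nm]] <- row[[nm]][1]
      }
    }
    ring <- zones$zones$ring[[k]]
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a zone system from GeoJSON
#'
#' Reads a FeatureCollection of Polygon features; the first ring of each
#' polygon is used (holes are not supported) and a unique `zone_id` property
#' is required on every feature.
#'
#' @param path path to a GeoJSON file.
#' @return a [zone_system()].
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_mobflow("expected a GeoJSON FeatureCollection")
  }
  ids <- character(length(gj$features))
  rings <- vector("list", length(gj$features))
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- f$properties$zone_id
    if (is.null(id)) stop_mobflow("every feature needs a zone_id property")
    ids[k] <- as.character(id)
    if (!identical(f$geometry$type, "Polygon")) {
      stop_mobflow("only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    rings[[k]] <- do.call(rbind, lapply(ring, function(pt) {
      c(lon = as.numeric(pt[[1]]), lat = as.numeric(pt[[2]]))
    }))
  }
  zone_system(ids, rings)
}
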