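# Lightweight planar geometry layer.
#
# Polygons are two-column matrices of (lon, lat) vertices, open (last vertex
# not repeated), without holes. A geometry is a list of such matrices.
# Restrictions, documented and asserted where cheap: clip regions must be
# convex (grid cells, bounding rectangles, Voronoi cells all are), and
# multi-part regions used as clip sets must not overlap among themselves.
# Areas are always computed in an equal-area projection, never in degrees.

EARTH_RADIUS_M <- 6371008.8

#' Project lon/lat degrees to an equal-area plane
#'
#' Cylindrical equal-area projection (Lambert, standard parallel `lat_ts`):
#' exact area preservation everywhere, which is all the package needs from a
#' projection. The standard parallel defaults to the mean latitude of the
#' coordinates so that shape distortion stays small at the study latitudes.
#'
#' @param coords Two-column matrix (lon, lat) in degrees, WGS84.
#' @param lat_ts Standard parallel in degrees.
#' @return Two-column matrix (x, y) in metres.
#' @export
ea_project <- function(coords, lat_ts = mean(coords[, 2])) {
  k <- cos(lat_ts * pi / 180)
  cbind(EARTH_RADIUS_M * (coords[, 1] * pi / 180) * k,
        EARTH_RADIUS_M * sin(coords[, 2] * pi / 180) / k)
}

# Signed shoelace area of an open ring, in the units of its coordinates^2.
ring_area_signed <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 3) return(0)
  x <- m[, 1]; y <- m[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon geometry in square metres
#'
#' @param polys A polygon matrix or list of polygon matrices (lon/lat).
#' @param lat_ts Standard parallel for the equal-area projection; defaults to
#'   the mean latitude of the geometry.
#' @return Area in m^2 (parts summed; orientation ignored).
#' @export
geom_area_m2 <- function(polys, lat_ts = NULL) {
  if (is.matrix(polys)) polys <- list(polys)
  polys <- Filter(function(p) !is.null(p) && nrow(p) >= 3, polys)
  if (length(polys) == 0) return(0)
  if (is.null(lat_ts)) lat_ts <- mean(unlist(lapply(polys, function(p) p[, 2])))
  sum(vapply(polys, function(p) abs(ring_area_signed(ea_project(p, lat_ts))),
             numeric(1)))
}

# Clip an arbitrary polygon by the half-plane a*x + b*y <= c
# (Sutherland-Hodgman edge step). Returns a matrix, possibly with < 3 rows.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c
  inside <- d <= 1e-12 * max(1, abs(c))
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (inside[i]) out <- rbind(out, p)
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

# Ensure counter-clockwise orientation.
ccw <- function(poly) if (ring_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly

#' Clip a polygon by a convex polygon
#'
#' Sutherland-Hodgman clipping: the subject polygon may be any simple
#' polygon; the clip polygon must be convex.
#'
#' @param subject Polygon matrix to clip.
#' @param clip Convex polygon matrix.
#' @return The clipped polygon matrix (0 rows when disjoint).
#' @export
clip_convex <- function(subject, clip) {
  cl <- ccw(clip)
  n <- nrow(cl)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # inward normal of CCW edge (p -> q): keep points left of the edge
    p <- cl[i, ]; q <- cl[j, ]
    a <- -(q[2] - p[2]); b <- q[1] - p[1]
    c <- a * p[1] + b * p[2]
    out <- clip_halfplane(out, -a, -b, -c)
    if (nrow(out) == 0) break
  }
  out
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Area of intersection of two geometries (lists of polygons). Each polygon of
# `clip_set` must be convex, and the members of `clip_set` must not overlap
# one another (otherwise the overlapped area is counted once per member).
intersection_area_m2 <- function(polys, clip_set, lat_ts = NULL) {
  if (is.matrix(polys)) polys <- list(polys)
  if (is.matrix(clip_set)) clip_set <- list(clip_set)
  if (is.null(lat_ts)) lat_ts <- mean(unlist(lapply(polys, function(p) p[, 2])))
  total <- 0
  for (p in polys) {
    for (cl in clip_set) {
      piece <- clip_convex(p, cl)
      if (nrow(piece) >= 3)
        total <- total + abs(ring_area_signed(ea_project(piece, lat_ts)))
    }
  }
  total
}

# Even-odd point-in-polygon over a list of polygons.
point_in_geom <- function(x, y, polys) {
  if (is.matrix(polys)) polys <- list(polys)
  inside <- rep(FALSE, length(x))
  for (p in polys) {
    n <- nrow(p)
    px <- p[, 1]; py <- p[, 2]
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1L
      cross <- (py[i] > y) != (py[j] > y)
      if (any(cross)) {
        xint <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
        flip <- cross & (x < xint)
        inside <- xor(inside, flip)
      }
    }
  }
  inside
}

#' Percentage of a habitat's range lying within the fished area
#'
#' The spatial-overlap attribute input: the share of the habitat's range
#' inside the fished area under assessment, relative to the habitat's entire
#' range within the management jurisdiction. All areas are computed in an
#' equal-area projection.
#'
#' @param habitat Habitat geometry (polygon matrix or list of them).
#' @param fished Fished-area geometry; each part must be convex and parts must
#'   not overlap.
#' @param jurisdiction Jurisdiction geometry, same restrictions.
#' @return Percentage in \[0, 100\].
#' @export
compute_overlap <- function(habitat, fished, jurisdiction) {
  denom <- intersection_area_m2(habitat, jurisdiction)
  if (denom <= 0)
    abort_validation("habitat has zero range within the jurisdiction")
  num <- intersection_area_m2(habitat, fished)
  min(100, max(0, 100 * num / denom))
}

#' Read a habitat map from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features in WGS84 with
#' properties `habitat` (label) and optionally `zone`. Holes (interior rings)
#' are not supported and raise an error.
#'
#' @param path GeoJSON file path.
#' @return A `ccsa_map` object: a list of features, each with `habitat_label`,
#'   `zone`, `polygons` (list of matrices) and `properties`.
#' @export
read_habitat_map <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    abort_validation("'%s' is not a GeoJSON FeatureCollection", path)
  features <- lapply(gj$features, function(f) {
    geom <- f$geometry
    rings_of <- function(poly_coords) {
      if (length(poly_coords) > 1)
        abort_validation("polygon holes are not supported")
      ring <- do.call(rbind, lapply(poly_coords[[1]], function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
      # drop closing vertex
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      ring
    }
    polygons <- switch(geom$type,
      Polygon = list(rings_of(geom$coordinates)),
      MultiPolygon = lapply(geom$coordinates, rings_of),
      abort_validation("unsupported geometry type '%s'", geom$type)
    )
    props <- f$properties
    list(habitat_label = props$habitat %||% props$habitat_label %||% NA_character_,
         zone = props$zone %||% NA_character_,
         polygons = polygons,
         properties = props)
  })
  structure(list(features = features), class = "ccsa_map")
}

#' Write a habitat map (with optional per-feature attributes) to GeoJSON
#'
#' @param map A `ccsa_map`.
#' @param path Output path.
#' @param extra Optional data.frame of per-feature attributes, one row per
#'   feature, merged into the properties (e.g. risk scores for mapping).
#' @return `path`, invisibly.
#' @export
write_habitat_map <- function(map, path, extra = NULL) {
  features <- lapply(seq_along(map$features), function(i) {
    f <- map$features[[i]]
    props <- f$properties %||% list()
    props$habitat <- f$habitat_label
    props$zone <- f$zone
    props$habitat_label <- NULL
    if (!is.null(extra)) for (nm in names(extra)) props[[nm]] <- extra[i, nm][[1]]
    coords <- lapply(f$polygons, function(p) {
      ring <- rbind(p, p[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(k) as.numeric(ring[k, ])))
    })
    list(type = "Feature",
         properties = props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @export
print.ccsa_map <- function(x, ...) {
  cat(sprintf("<ccsa_map> %d feature(s); habitats: %s\n",
              length(x$features),
              paste(unique(vapply(x$features, `[[`, "", "habitat_label")),
                    collapse = ", ")))
  invisible(x)
}

# All polygons of a map belonging to one habitat label.
map_geometry <- function(map, habitat_label) {
  polys <- list()
  for (f in map$features) {
    if (identical(f$habitat_label, habitat_label)) polys <- c(polys, f$polygons)
  }
  polys
}

map_labels <- function(map) {
  unique(vapply(map$features, `[[`, "", "habitat_label"))
}
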