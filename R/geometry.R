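# Planar polygon primitives used by the commune map generator and the
# Voronoi overlap-weight aggregation. All coordinates are projected km.
# Polygons are n x 2 matrices of vertices, implicitly closed, any orientation.

#' Polygon area (shoelace formula)
#'
#' @param poly numeric matrix with two columns (x, y); vertices in order,
#'   implicitly closed.
#' @return Non-negative area in squared coordinate units.
#' @export
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid; falls back to the vertex mean for degenerate
#' (near zero area) polygons.
#' @param poly vertex matrix as in [poly_area()].
#' @return length-2 numeric (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Clip a polygon against the half-plane a*x + b*y <= c (Sutherland-Hodgman
# step). Returns NULL when the intersection is empty.
clip_halfplane <- function(poly, a, b, cc, eps = 1e-9) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  n <- nrow(poly)
  val <- a * poly[, 1] + b * poly[, 2] - cc
  inside <- val <= eps
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  out <- matrix(0, n * 2, 2)
  k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1; out[k, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- val[i] / (val[i] - val[j])
      k <- k + 1
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k < 3) return(NULL)
  out[seq_len(k), , drop = FALSE]
}

#' Intersect a simple polygon with a convex polygon
#'
#' Sutherland-Hodgman clipping: the subject polygon is clipped against the
#' half-plane of every edge of the convex polygon. Used for the
#' commune-by-antenna-cell overlap areas.
#'
#' @param subject vertex matrix of a simple polygon.
#' @param convex vertex matrix of a convex polygon (any orientation).
#' @return vertex matrix of the intersection, or NULL when empty.
#' @export
clip_polygon_convex <- function(subject, convex) {
  if (is.null(subject) || is.null(convex) || nrow(convex) < 3) return(NULL)
  # ensure counter-clockwise orientation of the clip polygon
  x <- convex[, 1]; y <- convex[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s < 0) convex <- convex[rev(seq_len(nrow(convex))), , drop = FALSE]
  poly <- subject
  n <- nrow(convex)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p1 <- convex[i, ]; p2 <- convex[j, ]
    # inside of a CCW edge: cross(p2-p1, z-p1) >= 0  <=>  a*x + b*y <= c
    a <- p2[2] - p1[2]
    b <- -(p2[1] - p1[1])
    cc <- a * p1[1] + b * p1[2]
    poly <- clip_halfplane(poly, a, b, cc)
    if (is.null(poly)) return(NULL)
  }
  poly
}

#' Bounded Voronoi tessellation
#'
#' Computes the Voronoi cell of every seed point, clipped to a rectangular
#' extent, by intersecting perpendicular-bisector half-planes. Cells are
#' convex and jointly tile the extent.
#'
#' @param points n x 2 matrix of seed coordinates (km).
#' @param extent numeric length 4: (xmin, xmax, ymin, ymax).
#' @return list of vertex matrices, one convex polygon per seed, in input
#'   order.
#' @export
voronoi_cells <- function(points, extent) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(ncol(points) == 2, length(extent) == 4,
            extent[2] > extent[1], extent[4] > extent[3])
  box <- rbind(c(extent[1], extent[3]), c(extent[2], extent[3]),
               c(extent[2], extent[4]), c(extent[1], extent[4]))
  if (n == 1) return(list(box))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    p <- points[i, ]
    d2 <- (points[, 1] - p[1])^2 + (points[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[ord != i & d2[ord] > 0]
    cell <- box
    maxr2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
    for (j in ord) {
      # a bisector at distance d/2 > max vertex radius cannot cut the cell;
      # neighbours are sorted by distance, so we can stop early
      if (d2[j] >= 4 * maxr2) break
      q <- points[j, ]
      a <- 2 * (q[1] - p[1]); b <- 2 * (q[2] - p[2])
      cc <- q[1]^2 + q[2]^2 - p[1]^2 - p[2]^2
      newcell <- clip_halfplane(cell, a, b, cc)
      if (is.null(newcell))
        stop("degenerate Voronoi cell: coincident seed points?")
      if (!identical(dim(newcell), dim(cell)) || !all(newcell == cell)) {
        cell <- newcell
        maxr2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
      }
    }
    cells[[i]] <- cell
  }
  cells
}

# --- GeoJSON I/O (FeatureCollection of Polygons / Points) -------------------

#' Write polygons with properties as GeoJSON
#'
#' @param polygons named list of vertex matrices.
#' @param properties data.frame, one row per polygon.
#' @param path output file.
#' @export
write_geojson_polygons <- function(polygons, properties, path) {
  stopifnot(length(polygons) == nrow(properties))
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    list(
      type = "Feature",
      properties = as.list(properties[i, , drop = FALSE]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) unname(ring[k, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write point features as GeoJSON
#'
#' @param coords n x 2 matrix of coordinates.
#' @param properties data.frame, one row per point.
#' @param path output file.
#' @export
write_geojson_points <- function(coords, properties, path) {
  stopifnot(nrow(coords) == nrow(properties))
  feats <- lapply(seq_len(nrow(coords)), function(i) {
    list(
      type = "Feature",
      properties = as.list(properties[i, , drop = FALSE]),
      geometry = list(type = "Point", coordinates = unname(coords[i, ]))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of polygons
#'
#' @param path GeoJSON file written by [write_geojson_polygons()] (or any
#'   FeatureCollection of simple, single-ring Polygons).
#' @return list with `polygons` (list of open vertex matrices) and
#'   `properties` (data.frame).
#' @export
read_geojson_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  polys <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    m
  })
  props <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  list(polygons = polys, properties = props)
}
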