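# Tract geometry: centroids, polygons, queen contiguity, GeoJSON I/O.
#
# All distance computations downstream (scan radii) are Euclidean, so
# coordinates must be planar. Geographic (lon/lat) input is detected
# heuristically and either rejected or reprojected with a local
# equirectangular projection on request.

#' Construct a tract geometry object
#'
#' @param tract_id Character vector of tract ids.
#' @param x,y Planar centroid coordinates (meters or other consistent
#'   linear units). If omitted and `polygons` is given, centroids are
#'   computed as polygon (shoelace) centroids.
#' @param polygons Optional named list (by tract id) of two-column
#'   coordinate matrices, one exterior ring each (first vertex need not be
#'   repeated).
#' @param crs Label recording the coordinate reference system; purely
#'   descriptive. `"planar"` (default) asserts projected coordinates.
#' @return A `tract_geometry` object.
#' @export
tract_geometry <- function(tract_id, x = NULL, y = NULL, polygons = NULL,
                           crs = "planar") {
  tract_id <- as.character(tract_id)
  if (anyDuplicated(tract_id)) {
    stop("tract_geometry: duplicate tract_id", call. = FALSE)
  }
  if (!is.null(polygons)) {
    if (!all(tract_id %in% names(polygons))) {
      stop("tract_geometry: polygons missing for some tracts",
        call. = FALSE)
    }
    polygons <- polygons[tract_id]
    for (id in tract_id) validate_ring(polygons[[id]], id)
    if (is.null(x)) {
      cen <- t(vapply(polygons, ring_centroid, numeric(2)))
      x <- cen[, 1]; y <- cen[, 2]
    }
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(tract_id) || length(y) != length(tract_id) ||
      any(!is.finite(x)) || any(!is.finite(y))) {
    stop("tract_geometry: centroids must be finite and one per tract",
      call. = FALSE)
  }
  structure(list(ids = tract_id, x = x, y = y, polygons = polygons,
    crs = crs), class = "tract_geometry")
}

#' @export
print.tract_geometry <- function(x, ...) {
  cat(sprintf("Tract geometry: %d tracts (%s)%s\n", length(x$ids), x$crs,
    if (is.null(x$polygons)) ", centroids only" else ", with polygons"))
  invisible(x)
}

# drop a repeated closing vertex; basic validity checks
validate_ring <- function(ring, id) {
  if (!is.matrix(ring) || ncol(ring) != 2 || !all(is.finite(ring))) {
    stop(sprintf("invalid polygon for tract '%s': need a finite n x 2 ring",
      id), call. = FALSE)
  }
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(ring) < 3) {
    stop(sprintf("invalid polygon for tract '%s': fewer than 3 vertices",
      id), call. = FALSE)
  }
  if (ring_self_intersects(ring)) {
    stop(sprintf("invalid polygon for tract '%s': self-intersecting ring",
      id), call. = FALSE)
  }
  ring
}

ring_centroid <- function(ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# proper-crossing test between all non-adjacent edge pairs
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  p1 <- ring
  p2 <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # edge n is adjacent to edge 1
    for (j in js) {
      if (segments_cross(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a, b, c, d) {
  orient <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  o1 <- orient(a, b, c); o2 <- orient(a, b, d)
  o3 <- orient(c, d, a); o4 <- orient(c, d, b)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Queen-contiguity adjacency from tract polygons
#'
#' Two tracts are neighbors if their polygons share at least one boundary
#' point, including a single corner vertex (queen rule). Contact is
#' detected by snapping every vertex to a tolerance grid and declaring
#' tracts adjacent when they share a snapped vertex; the tolerance absorbs
#' coordinate jitter between file dialects. Boundary contact occurring only
#' at a point interior to both polygons' edges (no shared vertex) is not
#' detected; tract tessellations from census products share vertices along
#' common boundaries, so this is the standard case.
#'
#' @param geometry A `tract_geometry` with polygons.
#' @param snap Snapping tolerance in map units (default `1e-6`).
#' @return An `adjacency` object (symmetric, no self-loops; isolated
#'   tracts retained and flagged by `print`).
#' @examples
#' g <- lattice_geometry(2, 2)
#' queen_adjacency(g)  # 6 undirected edges: rook pairs + both diagonals
#' @export
queen_adjacency <- function(geometry, snap = 1e-6) {
  if (is.null(geometry$polygons)) {
    stop("queen_adjacency requires polygons", call. = FALSE)
  }
  ids <- geometry$ids
  keys <- lapply(geometry$polygons, function(ring) {
    ring <- validate_ring(ring, "?")
    unique(paste(round(ring[, 1] / snap), round(ring[, 2] / snap)))
  })
  vert <- data.frame(
    key = unlist(keys, use.names = FALSE),
    tract = rep(ids, lengths(keys)),
    stringsAsFactors = FALSE)
  groups <- split(vert$tract, vert$key)
  groups <- groups[lengths(groups) > 1]
  a <- character(0); b <- character(0)
  for (g in groups) {
    g <- sort(unique(g))
    if (length(g) < 2) next
    pr <- utils::combn(g, 2)
    a <- c(a, pr[1, ]); b <- c(b, pr[2, ])
  }
  make_adjacency(a, b, tract_ids = ids)
}

#' Unit-square lattice geometry
#'
#' Builds an `nrow` x `ncol` grid of unit-square tracts — the reference
#' geometry used by the synthetic registry generator and by tests. Tract
#' ids are `"r-c"` (row-column, 1-based); coordinates are in abstract map
#' units treated as kilometers by the scan's radius reporting.
#'
#' @param nrow,ncol Lattice dimensions.
#' @return A `tract_geometry` with polygons.
#' @export
lattice_geometry <- function(nrow, ncol) {
  ids <- as.vector(outer(seq_len(nrow), seq_len(ncol),
    function(r, c) sprintf("%02d-%02d", r, c)))
  rr <- rep(seq_len(nrow), times = ncol)
  cc <- rep(seq_len(ncol), each = nrow)
  polys <- Map(function(r, c) {
    cbind(c(c - 1, c, c, c - 1), c(r - 1, r - 1, r, r))
  }, rr, cc)
  names(polys) <- ids
  tract_geometry(ids, polygons = polys)
}

looks_geographic <- function(geometry) {
  all(abs(geometry$x) <= 180) && all(abs(geometry$y) <= 90) &&
    !identical(geometry$crs, "planar")
}

#' Project geographic centroids to a local planar system
#'
#' Equirectangular projection about the mean latitude: adequate for a
#' single-state study region where the scan needs Euclidean distances in
#' meters. For rigorous work reproject upstream with a proper GIS
#' projection and supply planar coordinates directly.
#'
#' @param geometry A `tract_geometry` whose `x`/`y` are lon/lat degrees.
#' @return A `tract_geometry` with coordinates in meters
#'   (`crs = "local-equirectangular"`). Polygons are dropped (adjacency
#'   should be derived before projecting).
#' @export
project_local <- function(geometry) {
  R <- 6371000
  lat0 <- mean(geometry$y) * pi / 180
  x <- R * (geometry$x * pi / 180) * cos(lat0)
  y <- R * (geometry$y * pi / 180)
  tract_geometry(geometry$ids, x - mean(x), y - mean(y),
    crs = "local-equirectangular")
}

#' Read tract polygons from a GeoJSON FeatureCollection
#'
#' Each feature must be a `Polygon` (exterior ring only; holes are
#' rejected) carrying a `tract_id` property.
#'
#' @param path GeoJSON file path.
#' @param crs CRS label to record (default `"planar"`).
#' @return A `tract_geometry` with polygons and shoelace centroids.
#' @export
read_tract_geojson <- function(path, crs = "planar") {
  j <- jsonlite::read_json(path)
  if (!identical(j$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  ids <- character(0); polys <- list()
  for (f in j$features) {
    id <- as.character(f$properties$tract_id)
    if (!length(id)) stop("feature without tract_id property",
      call. = FALSE)
    if (!identical(f$geometry$type, "Polygon")) {
      stop(sprintf("tract '%s': only Polygon geometries are supported", id),
        call. = FALSE)
    }
    rings <- f$geometry$coordinates
    if (length(rings) != 1) {
      stop(sprintf("tract '%s': polygons with holes are not supported", id),
        call. = FALSE)
    }
    ring <- do.call(rbind, lapply(rings[[1]], function(pt) {
      as.numeric(unlist(pt)[1:2])
    }))
    ids <- c(ids, id)
    polys[[id]] <- ring
  }
  tract_geometry(ids, polygons = polys, crs = crs)
}

geojson_polygon <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- rbind(ring, ring[1, ])
  }
  list(type = "Polygon",
    coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
      c(ring[i, 1], ring[i, 2])
    })))
}

#' Write tract polygons to GeoJSON
#' @param geometry A `tract_geometry` with polygons.
#' @param path Output file path.
#' @export
write_tract_geojson <- function(geometry, path) {
  feats <- lapply(geometry$ids, function(id) {
    list(type = "Feature",
      properties = list(tract_id = id),
      geometry = geojson_polygon(geometry$polygons[[id]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export detected clusters as GeoJSON
#'
#' Writes one feature per tract belonging to a retained cluster; each
#' feature carries the cluster's rank, detected years, observed and
#' expected counts, both relative-risk measures, log-likelihood ratio and
#' Monte Carlo p-value as properties, so the file renders directly in any
#' GIS viewer.
#'
#' @param result An `st_scan` result (see [st_scan()]).
#' @param geometry A `tract_geometry` with polygons for every cluster
#'   tract.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cluster_geojson <- function(result, geometry, path) {
  feats <- list()
  for (cl in result$clusters) {
    missing <- setdiff(cl$tracts, geometry$ids)
    if (length(missing)) {
      stop("no geometry for cluster tract(s): ",
        paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    for (id in cl$tracts) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(
          tract_id = id, rank = cl$rank,
          year_start = cl$year_start, year_end = cl$year_end,
          observed = cl$observed, expected = cl$expected,
          rr = cl$rr, rr_adjusted = cl$rr_adjusted,
          llr = cl$llr, p_value = cl$p_value),
        geometry = geojson_polygon(geometry$polygons[[id]]))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
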