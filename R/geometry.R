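# Planar geometry helpers: local metric projection and polyline operations.
# All along-track / distance computations are carried out in a projected
# plane with coordinates in meters.

# meters per degree of latitude (pi/180 * mean Earth radius, 6371.0088 km)
.M_PER_DEG <- 111194.93

#' Project geographic coordinates onto a local metric plane
#'
#' An equirectangular projection about a fixed origin: one degree of latitude
#' maps to ~111.195 km and one degree of longitude to the same scaled by the
#' cosine of the origin latitude. Adequate for study areas a few degrees
#' across, which is the scale of a wintering-survey block; lengths are
#' meter-true near the origin latitude.
#'
#' @param lon,lat numeric vectors of geographic coordinates (degrees).
#' @param origin length-2 numeric, `c(lon0, lat0)`, the projection origin.
#' @return A two-column matrix with columns `x`, `y` in meters.
#' @seealso [unproject_xy()]
#' @export
project_lonlat <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  kx <- .M_PER_DEG * cos(origin[2] * pi / 180)
  cbind(x = (lon - origin[1]) * kx, y = (lat - origin[2]) * .M_PER_DEG)
}

#' Inverse of [project_lonlat()]
#'
#' @param x,y numeric vectors of planar coordinates (meters).
#' @param origin the same origin used to project.
#' @return A two-column matrix with columns `lon`, `lat` in degrees.
#' @export
unproject_xy <- function(x, y, origin) {
  stopifnot(length(origin) == 2)
  kx <- .M_PER_DEG * cos(origin[2] * pi / 180)
  cbind(lon = origin[1] + x / kx, lat = origin[2] + y / .M_PER_DEG)
}

# segment lengths and cumulative arc length of a polyline (n x 2 matrix)
path_cumlen <- function(path) {
  d <- sqrt(rowSums(diff(path)^2))
  c(0, cumsum(d))
}

path_length <- function(path) {
  cl <- path_cumlen(path)
  cl[length(cl)]
}

# point on the polyline at arc length s (s clamped to [0, L])
path_point_at <- function(path, s) {
  cl <- path_cumlen(path)
  L <- cl[length(cl)]
  s <- pmin(pmax(s, 0), L)
  # index of segment containing s (half-open; s = L falls in last segment)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(path) - 1L)
  seg <- cl[i + 1L] - cl[i]
  t <- ifelse(seg > 0, (s - cl[i]) / seg, 0)
  path[i, , drop = FALSE] + (path[i + 1L, , drop = FALSE] - path[i, , drop = FALSE]) * t
}

#' Project points onto a polyline
#'
#' For each point, finds the nearest location on the polyline and returns the
#' along-track arc length of that location together with the (unsigned)
#' offset distance. Interior points see the perpendicular distance; points
#' beyond an endpoint see the distance to that endpoint.
#'
#' @param points n x 2 matrix of planar point coordinates (meters).
#' @param path m x 2 matrix of polyline vertices (meters), m >= 2.
#' @return A data.frame with columns `along` (meters along the line,
#'   clamped to `[0, L]`), `offset` (meters from the line) and `along_raw`
#'   (the unclamped along-track coordinate on the nearest segment: negative
#'   before the start, greater than `L` past the end; used to reject points
#'   that lie beyond the line's endpoints).
#' @export
project_onto_path <- function(points, path) {
  points <- rbind(points)  # coerce vectors / data.frames
  stopifnot(ncol(points) == 2, nrow(path) >= 2)
  cl <- path_cumlen(path)
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_al <- numeric(n)
  best_raw <- numeric(n)
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]
    b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    traw <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(traw, 0), 1)
    dx <- points[, 1] - (a[1] + t * ab[1])
    dy <- points[, 2] - (a[2] + t * ab[2])
    d2 <- dx * dx + dy * dy
    # strict < keeps the earliest segment on exact ties (shared vertices)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_al[upd] <- cl[i] + t[upd] * sqrt(len2)
    best_raw[upd] <- cl[i] + traw[upd] * sqrt(len2)
  }
  data.frame(along = best_al, offset = sqrt(best_d2), along_raw = best_raw)
}

# minimum distance (meters) from each point to a set of polylines
min_dist_to_polylines <- function(points, polylines) {
  points <- rbind(points)
  d <- rep(Inf, nrow(points))
  for (pl in polylines) {
    if (nrow(pl) == 1L) {
      di <- sqrt((points[, 1] - pl[1, 1])^2 + (points[, 2] - pl[1, 2])^2)
    } else {
      di <- project_onto_path(points, pl)$offset
    }
    d <- pmin(d, di)
  }
  d
}
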