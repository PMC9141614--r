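# Planar geometry primitives.
#
# All coordinates are projected planar meters: the buffers and distances in
# this package are metric, so no geographic (lat/lon) math appears anywhere.
# Polygons are n x 2 matrices of vertices (open ring: first vertex NOT
# repeated at the end), oriented either way unless stated.

#' Polygon area (shoelace formula)
#'
#' @param poly numeric matrix (n x 2) of polygon vertices, open ring.
#' @return Area in square meters (always non-negative).
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Boundary-inclusive point-in-polygon test
#'
#' Ray-casting with an explicit on-boundary check so that points lying
#' exactly on an edge or vertex count as inside (the pipeline's
#' deterministic tie rule for buffer membership).
#'
#' @param px,py numeric vectors of point coordinates (same length).
#' @param poly polygon matrix (n x 2), open ring.
#' @param tol boundary snap tolerance in meters.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  stopifnot(length(px) == length(py))
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  inside <- logical(length(px))
  onb <- logical(length(px))
  for (e in seq_len(n)) {
    # on-segment check
    d <- .dist_point_segment(px, py, ax[e], ay[e], bx[e], by[e])
    onb <- onb | d <= tol
    # ray casting (half-open rule on y to avoid double-counting vertices)
    crosses <- ((ay[e] > py) != (by[e] > py))
    if (any(crosses)) {
      xint <- ax[e] + (py - ay[e]) / (by[e] - ay[e]) * (bx[e] - ax[e])
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  inside | onb
}

# distance from points (px, py) to the segment (ax, ay)-(bx, by); vectorized
# over points, scalar segment
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  cx <- ax + t * dx; cy <- ay + t * dy
  sqrt((px - cx)^2 + (py - cy)^2)
}

#' Euclidean distance from points to a polygon
#'
#' Zero for points inside or on the boundary; otherwise the minimum distance
#' to any edge. This is the exact membership predicate for a buffered
#' polygon: \code{dist <= r} iff the point lies in the outward Euclidean
#' buffer of radius \code{r} (interior included), for any simple polygon.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances in meters.
#' @export
point_polygon_distance <- function(px, py, poly) {
  stopifnot(length(px) == length(py))
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  d <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    d <- pmin(d, .dist_point_segment(px, py, ax[e], ay[e], bx[e], by[e]))
  }
  d[point_in_polygon(px, py, poly)] <- 0
  d
}

# TRUE if the (open-ring) polygon is convex; collinear runs allowed
.is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(2:n, 1); i3 <- c(3:n, 1, 2)
  cross <- (x[i2] - x) * (y[i3] - y[i2]) - (y[i2] - y) * (x[i3] - x[i2])
  all(cross >= -1e-9 * max(abs(cross), 1)) || all(cross <= 1e-9 * max(abs(cross), 1))
}

# ensure counter-clockwise orientation (signed shoelace > 0)
.ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  if (sum(x * ys - xs * y) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Outward Euclidean buffer of a convex polygon
#'
#' Returns the Minkowski sum of the polygon with a disc of radius
#' \code{radius_m}: offset edges joined by circular arcs at the vertices,
#' discretized with \code{n_arc} segments per quarter turn. Radius 0 returns
#' the polygon unchanged. Exact (up to arc discretization) for convex input;
#' non-convex polygons are rejected — buffer membership tests elsewhere in
#' the package use \code{\link{point_polygon_distance}}, which handles any
#' simple polygon exactly.
#'
#' @param poly convex polygon matrix (n x 2), open ring.
#' @param radius_m buffer radius in meters, >= 0.
#' @param n_arc arc segments per quarter turn (controls area accuracy).
#' @return Polygon matrix (m x 2), open ring, counter-clockwise.
#' @export
buffered_boundary <- function(poly, radius_m, n_arc = 64L) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  if (!is.finite(radius_m) || radius_m < 0) {
    stop("buffer radius must be a non-negative finite number")
  }
  if (anyNA(poly)) stop("invalid geometry: NA vertex coordinates")
  if (polygon_area(poly) <= 0) stop("invalid geometry: zero-area polygon")
  if (radius_m == 0) return(poly)
  if (!.is_convex(poly)) {
    stop("buffered_boundary supports convex polygons; use point_polygon_distance for membership in buffers of non-convex polygons")
  }
  p <- .ccw(poly)
  # drop exactly repeated consecutive vertices
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  p <- p[keep, , drop = FALSE]
  n <- nrow(p)
  nxt <- c(2:n, 1)
  ex <- p[nxt, 1] - p[, 1]; ey <- p[nxt, 2] - p[, 2]
  elen <- sqrt(ex^2 + ey^2)
  # outward normal of each CCW edge is (ey, -ex)/len
  nx <- ey / elen; ny <- -ex / elen
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    # arc at vertex i from previous edge normal to this edge normal
    a0 <- atan2(ny[prev], nx[prev])
    a1 <- atan2(ny[i], nx[i])
    sweep <- (a1 - a0) %% (2 * pi)
    if (sweep > 1e-12) {
      k <- max(2L, ceiling(sweep / (pi / 2) * n_arc) + 1L)
      ang <- a0 + sweep * seq(0, 1, length.out = k)
      out[[2L * i - 1L]] <- cbind(p[i, 1] + radius_m * cos(ang),
                                  p[i, 2] + radius_m * sin(ang))
    }
    # offset edge from vertex i to vertex nxt[i]
    out[[2L * i]] <- rbind(c(p[i, 1] + radius_m * nx[i], p[i, 2] + radius_m * ny[i]),
                           c(p[nxt[i], 1] + radius_m * nx[i], p[nxt[i], 2] + radius_m * ny[i]))
  }
  ring <- do.call(rbind, out)
  # remove consecutive duplicates introduced at arc/edge joins
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 1e-12)
  ring <- ring[keep, , drop = FALSE]
  if (sqrt(sum((ring[1, ] - ring[nrow(ring), ])^2)) < 1e-12) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  unname(ring)
}

#' Polygon centroid (area-weighted)
#'
#' @param poly polygon matrix (n x 2), open ring.
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  p <- .ccw(poly)
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}
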