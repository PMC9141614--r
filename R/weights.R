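# Spatial weights: sparse neighbor structure with optional row
# standardization. Queen contiguity (any shared boundary point) is the
# default, matching common practice for polygon lattices; k-nearest-neighbor
# weights are offered for sensitivity analysis.

#' Construct a spatial_weights object
#'
#' @param neighbors list of integer vectors (neighbor indices per unit).
#' @param weights list of numeric vectors (same shape as \code{neighbors}).
#' @param row_standardized logical flag.
#' @return A \code{spatial_weights} object with fields \code{n},
#'   \code{neighbors}, \code{weights}, \code{row_standardized}, \code{S0}
#'   (total weight) and \code{islands} (indices with no neighbors).
#' @export
spatial_weights <- function(neighbors, weights = NULL, row_standardized = FALSE) {
  n <- length(neighbors)
  if (is.null(weights)) weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  stopifnot(length(weights) == n)
  for (i in seq_len(n)) {
    if (length(neighbors[[i]]) != length(weights[[i]])) stop("neighbors/weights shape mismatch")
    if (any(neighbors[[i]] == i)) stop("self-neighbors are not allowed (w_ii must be 0)")
    if (any(weights[[i]] < 0)) stop("weights must be non-negative")
  }
  S0 <- sum(unlist(weights, use.names = FALSE))
  if (n > 0 && S0 <= 0) stop("all-zero weights: S0 must be positive")
  structure(list(n = n, neighbors = neighbors, weights = weights,
                 row_standardized = row_standardized, S0 = S0,
                 islands = which(vapply(neighbors, length, 0L) == 0L)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- vapply(x$neighbors, length, 0L)
  cat(sprintf("spatial_weights: n = %d, avg neighbors %.2f, %s, %d island(s), S0 = %.4f\n",
              x$n, mean(k), if (x$row_standardized) "row-standardized" else "binary/raw",
              length(x$islands), x$S0))
  invisible(x)
}

#' Queen contiguity weights for polygons
#'
#' Two polygons are neighbors iff they share at least one boundary point —
#' an edge segment or a single vertex — within a snap tolerance. Computed
#' from minimum edge-to-edge distance with a bounding-box prefilter.
#' Symmetric, binary. Islands (no neighbors) are allowed and reported via a
#' warning.
#'
#' @param polygons list of polygon matrices (n x 2, open rings),
#'   non-overlapping.
#' @param snap_m snap tolerance in meters (default 1e-6).
#' @return A binary \code{\link{spatial_weights}} object.
#' @export
queen_weights <- function(polygons, snap_m = 1e-6) {
  n <- length(polygons)
  if (n < 2) stop("queen weights need at least 2 polygons")
  boxes <- t(vapply(polygons, function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])),
                    numeric(4)))
  nb <- lapply(seq_len(n), function(i) integer())
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # bounding boxes must come within snap distance
      if (boxes[i, 1] > boxes[j, 3] + snap_m || boxes[j, 1] > boxes[i, 3] + snap_m ||
          boxes[i, 2] > boxes[j, 4] + snap_m || boxes[j, 2] > boxes[i, 4] + snap_m) next
      if (.polys_touch(polygons[[i]], polygons[[j]], snap_m)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  w <- spatial_weights(nb)
  if (length(w$islands) > 0) {
    warning(sprintf("%d island polygon(s) with no neighbors: %s",
                    length(w$islands), paste(w$islands, collapse = ", ")))
  }
  w
}

# do two polygon boundaries come within tol of each other?
.polys_touch <- function(a, b, tol) {
  na <- nrow(a); nb_ <- nrow(b)
  a2 <- a[c(2:na, 1), , drop = FALSE]
  b2 <- b[c(2:nb_, 1), , drop = FALSE]
  for (i in seq_len(na)) {
    d <- .segments_min_dist(a[i, 1], a[i, 2], a2[i, 1], a2[i, 2],
                            b[, 1], b[, 2], b2[, 1], b2[, 2])
    if (any(d <= tol)) return(TRUE)
  }
  FALSE
}

# min distance between one segment (p1-p2) and many segments (q1-q2);
# vectorized over the q segments. Segments here never cross (disjoint
# polygon interiors), so endpoint-to-segment distances suffice.
.segments_min_dist <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  d1 <- .dist_point_segment(q1x, q1y, p1x, p1y, p2x, p2y)
  d2 <- .dist_point_segment(q2x, q2y, p1x, p1y, p2x, p2y)
  d3 <- mapply(function(ax, ay, bx, by) .dist_point_segment(p1x, p1y, ax, ay, bx, by),
               q1x, q1y, q2x, q2y)
  d4 <- mapply(function(ax, ay, bx, by) .dist_point_segment(p2x, p2y, ax, ay, bx, by),
               q1x, q1y, q2x, q2y)
  pmin(d1, d2, d3, d4)
}

#' k-nearest-neighbor weights from centroids
#'
#' w_ij = 1 for the k nearest centroids of unit i; distance ties are broken
#' by lower index, so the result is deterministic even with duplicate
#' centroids. Generally asymmetric; never produces islands.
#'
#' @param centroids numeric matrix (n x 2).
#' @param k number of neighbors, 1 <= k < n.
#' @return A binary \code{\link{spatial_weights}} object.
#' @export
knn_weights <- function(centroids, k) {
  n <- nrow(centroids)
  if (!is.finite(k) || k <= 0) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of units")
  k <- as.integer(k)
  d <- as.matrix(stats::dist(centroids))
  nb <- lapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    cand[order(d[i, cand], cand)][seq_len(k)]
  })
  spatial_weights(nb)
}

#' Row-standardize spatial weights
#'
#' Divides each non-island row by its sum so rows sum to one. Island rows
#' stay zero (they are excluded from statistics downstream with a logged
#' count). Idempotent.
#'
#' @param W a \code{\link{spatial_weights}} object.
#' @return Row-standardized \code{spatial_weights}.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  weights <- lapply(W$weights, function(wi) {
    s <- sum(wi)
    if (s > 0) wi / s else wi
  })
  spatial_weights(W$neighbors, weights, row_standardized = TRUE)
}

#' Dense matrix form of spatial weights
#'
#' @param W a \code{\link{spatial_weights}} object.
#' @return n x n numeric matrix with zero diagonal.
#' @export
weights_matrix <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  m <- matrix(0, W$n, W$n)
  for (i in seq_len(W$n)) m[i, W$neighbors[[i]]] <- W$weights[[i]]
  m
}
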