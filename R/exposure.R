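# Community-level green space exposure within walking-time buffers.
#
# The 15-minute-city operationalization: a buffer radius is walking minutes
# times walking speed (72 m/min by default), drawn outward from the
# community boundary; community exposure is the unweighted mean GVI of all
# kept sample points inside the buffered boundary (boundary-inclusive).

#' Walking-buffer radius
#'
#' @param minutes walking time, minutes (> 0); the study grid is 5, 10, 15,
#'   30.
#' @param walking_speed meters per minute, default 72.
#' @return Radius in meters (exact product).
#' @export
buffer_radius <- function(minutes, walking_speed = 72) {
  if (any(!is.finite(minutes)) || any(minutes <= 0)) stop("minutes must be positive")
  if (!is.finite(walking_speed) || walking_speed <= 0) stop("walking_speed must be positive")
  minutes * walking_speed
}

#' Mean GVI of sample points within a buffered community boundary
#'
#' Membership is boundary-inclusive: a point exactly on the buffer edge
#' counts as inside (deterministic tie rule). With \code{radius_m = 0} the
#' polygon itself is the buffer. If no point falls inside, the value is
#' missing (NA), never zero.
#'
#' @param boundary community polygon matrix (n x 2, open ring).
#' @param points data.frame with columns \code{x}, \code{y}, \code{gvi}
#'   (kept points only, gvi non-missing).
#' @param radius_m outward buffer radius in meters (>= 0).
#' @return List with \code{gvi} (mean or NA) and \code{n_points}.
#' @export
community_gvi <- function(boundary, points, radius_m = 0) {
  stopifnot(all(c("x", "y", "gvi") %in% names(points)))
  if (any(is.na(points$gvi))) stop("points must carry GVI (run QC first)")
  inside <- if (radius_m == 0) {
    point_in_polygon(points$x, points$y, boundary)
  } else {
    point_polygon_distance(points$x, points$y, boundary) <= radius_m
  }
  n <- sum(inside)
  list(gvi = if (n == 0) NA_real_ else mean(points$gvi[inside]), n_points = n)
}

#' Community x buffer exposure table
#'
#' Computes, for every community and every walking-time buffer, the mean GVI
#' of the kept sample points within the buffered boundary. Cells with no
#' points are flagged missing. Point-to-polygon distances are computed once
#' and thresholded per radius, so point sets are exactly nested across
#' radii.
#'
#' @param communities named list of community polygons (n x 2 matrices).
#' @param points data.frame of kept sample points (\code{id}, \code{x},
#'   \code{y}, \code{gvi}).
#' @param buffer_minutes walking times in minutes, default c(5, 10, 15, 30).
#' @param walking_speed meters per minute, default 72.
#' @return data.frame: community_id, minutes, radius_m, n_points, gvi.
#' @export
exposure_table <- function(communities, points,
                           buffer_minutes = c(5, 10, 15, 30),
                           walking_speed = 72) {
  if (length(communities) == 0) stop("no communities supplied")
  stopifnot(all(c("x", "y", "gvi") %in% names(points)))
  if (any(is.na(points$gvi))) stop("points must carry GVI (run QC first)")
  radii <- buffer_radius(buffer_minutes, walking_speed)
  ids <- names(communities)
  if (is.null(ids)) ids <- as.character(seq_along(communities))
  rows <- vector("list", length(communities) * length(radii))
  k <- 0L
  for (ci in seq_along(communities)) {
    d <- point_polygon_distance(points$x, points$y, communities[[ci]])
    for (bi in seq_along(radii)) {
      inside <- d <= radii[bi]
      n <- sum(inside)
      k <- k + 1L
      rows[[k]] <- data.frame(
        community_id = ids[ci], minutes = buffer_minutes[bi],
        radius_m = radii[bi], n_points = n,
        gvi = if (n == 0) NA_real_ else mean(points$gvi[inside])
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
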