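# Synthetic study region: street grid, sample points, planted greenness
# field, community tessellation and rental prices with a planted spatial
# association. Everything is deterministic under a fixed seed so every
# downstream stage of the pipeline is testable with known ground truth.

#' Generate a jittered street grid
#'
#' Builds horizontal and vertical street polylines spaced \code{spacing_m}
#' apart across a rectangular extent. Grid vertices (street intersections)
#' may be jittered by a fraction of the spacing; the jitter is applied to
#' the shared vertex grid, so crossing streets still meet at the same
#' (jittered) intersection. Vertices are clamped into the extent.
#'
#' @param extent_m numeric length-4 \code{c(xmin, ymin, xmax, ymax)} in meters.
#' @param spacing_m distance between parallel streets, meters.
#' @param jitter fraction of \code{spacing_m} by which interior vertices are
#'   perturbed uniformly in x and y (0 = perfect grid).
#' @param seed integer RNG seed.
#' @return A \code{street_network}: list with \code{segments} (list of
#'   polyline matrices, n x 2) and \code{extent}.
#' @export
generate_street_grid <- function(extent_m, spacing_m, jitter = 0, seed = 1L) {
  stopifnot(length(extent_m) == 4)
  if (!is.finite(spacing_m) || spacing_m <= 0) stop("spacing_m must be positive")
  w <- extent_m[3] - extent_m[1]; h <- extent_m[4] - extent_m[2]
  if (spacing_m >= min(w, h)) stop("spacing_m must be smaller than the extent's smaller side")
  if (jitter < 0 || jitter > 0.45) stop("jitter must be in [0, 0.45]")
  xs <- seq(extent_m[1], extent_m[3], by = spacing_m)
  ys <- seq(extent_m[2], extent_m[4], by = spacing_m)
  set.seed(as.integer(seed))
  vx <- outer(rep(1, length(ys)), xs)   # rows = y index, cols = x index
  vy <- outer(ys, rep(1, length(xs)))
  if (jitter > 0) {
    vx <- vx + matrix(stats::runif(length(vx), -jitter, jitter) * spacing_m, nrow(vx))
    vy <- vy + matrix(stats::runif(length(vy), -jitter, jitter) * spacing_m, nrow(vy))
    vx <- pmin(pmax(vx, extent_m[1]), extent_m[3])
    vy <- pmin(pmax(vy, extent_m[2]), extent_m[4])
  }
  segs <- c(
    lapply(seq_along(ys), function(i) cbind(vx[i, ], vy[i, ])),           # horizontal
    lapply(seq_along(xs), function(j) cbind(vx[, j], vy[, j]))            # vertical
  )
  structure(list(segments = segs, extent = as.numeric(extent_m)),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  len <- sum(vapply(x$segments, function(s) sum(sqrt(rowSums(diff(s)^2))), 0))
  cat(sprintf("street_network: %d polylines, total length %.1f km, extent [%g, %g] x [%g, %g] m\n",
              length(x$segments), len / 1000,
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  invisible(x)
}

#' Place sample points along a street network
#'
#' Points are placed along each polyline at arc-length multiples of
#' \code{interval_m}, always including both endpoints. Duplicate points at
#' street intersections are removed by exact coordinate match after rounding
#' to 1e-6 m (a deterministic, tolerance-free rule).
#'
#' @param network a \code{street_network}.
#' @param interval_m sampling interval along streets, meters (the study
#'   design samples every 200 m, densified to 50 m where needed).
#' @return data.frame with columns \code{id}, \code{x}, \code{y}.
#' @export
sample_points <- function(network, interval_m) {
  if (!is.finite(interval_m) || interval_m <= 0) stop("interval_m must be positive")
  pts <- lapply(network$segments, function(seg) {
    d <- sqrt(rowSums(diff(seg)^2))
    if (sum(d) == 0) return(NULL)
    cum <- c(0, cumsum(d))
    total <- cum[length(cum)]
    s <- unique(c(seq(0, total, by = interval_m), total))
    cbind(stats::approx(cum, seg[, 1], xout = s, ties = "ordered")$y,
          stats::approx(cum, seg[, 2], xout = s, ties = "ordered")$y)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0) {
    return(data.frame(id = integer(), x = numeric(), y = numeric()))
  }
  key <- paste(round(pts[, 1], 6), round(pts[, 2], 6))
  pts <- pts[!duplicated(key), , drop = FALSE]
  data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2])
}

#' Plant a spatial greenness field
#'
#' The field is a deterministic linear trend plus kernel-smoothed white
#' noise, clipped to [0, 1]: g(x, y) = clip(a0 + ax*x + ay*y + s(x, y)).
#' The smooth component s is a Gaussian-kernel weighted average of
#' iid Normal(0, noise_sd) values at random knots, so its pointwise scale is
#' about \code{noise_sd} and its correlation length is \code{length_scale}.
#' The trend emulates the center-to-periphery greenness gradient seen in
#' dense old urban cores versus newly built districts.
#'
#' @param extent_m study extent \code{c(xmin, ymin, xmax, ymax)}.
#' @param trend length-3 numeric \code{c(intercept, slope_x, slope_y)}; the
#'   slopes are per meter.
#' @param length_scale smoothness length scale of the noise, meters.
#' @param noise_sd standard deviation of the knot values (0 = pure trend).
#' @param n_knots number of noise knots.
#' @param seed integer RNG seed.
#' @return A \code{green_field}: list with an \code{eval(x, y)} function and
#'   the generating parameters.
#' @export
plant_green_field <- function(extent_m, trend = c(0.25, 0, 0),
                              length_scale = 1500, noise_sd = 0,
                              n_knots = 64L, seed = 1L) {
  stopifnot(length(extent_m) == 4, length(trend) == 3)
  if (!all(is.finite(c(trend, length_scale, noise_sd)))) stop("field parameters must be finite")
  if (length_scale <= 0) stop("length_scale must be positive")
  set.seed(as.integer(seed))
  kx <- stats::runif(n_knots, extent_m[1], extent_m[3])
  ky <- stats::runif(n_knots, extent_m[2], extent_m[4])
  kv <- stats::rnorm(n_knots, 0, noise_sd)
  eval_fun <- function(x, y) {
    g <- trend[1] + trend[2] * x + trend[3] * y
    if (noise_sd > 0) {
      # kernel-weighted average of knot values
      d2 <- outer(x, kx, "-")^2 + outer(y, ky, "-")^2
      w <- exp(-d2 / (2 * length_scale^2))
      g <- g + rowSums(w * rep(kv, each = length(x))) / pmax(rowSums(w), 1e-300)
    }
    pmin(1, pmax(0, g))
  }
  structure(list(eval = eval_fun, trend = trend, length_scale = length_scale,
                 noise_sd = noise_sd, n_knots = n_knots, seed = as.integer(seed)),
            class = "green_field")
}

#' Render synthetic street-view label images for one sample point
#'
#' Emits \code{n_views} pixel-class rasters (one per cardinal heading) in
#' which the pooled number of green-class pixels across all views equals
#' \code{round(target_fraction * n_views * H * W)} exactly. Green pixels are
#' placed pseudo-randomly across the pooled pixel grid and assigned one of
#' the vegetation classes (tree/grass/shrub); the rest get non-green urban
#' classes (sky/building/road).
#'
#' @param target_fraction planted green fraction in [0, 1].
#' @param image_shape integer length-2 \code{c(H, W)} in pixels.
#' @param n_views number of views (cardinal headings), default 4.
#' @param seed integer RNG seed.
#' @return List of \code{n_views} \code{\link{label_image}} objects, named
#'   by heading ("0", "90", ...).
#' @export
render_views <- function(target_fraction, image_shape = c(80L, 60L),
                         n_views = 4L, seed = 1L) {
  if (!is.finite(target_fraction) || target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must be in [0, 1]")
  }
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  stopifnot(h >= 1, w >= 1, n_views >= 1)
  set.seed(as.integer(seed))
  total <- n_views * h * w
  n_green <- round(target_fraction * total)
  cls <- sample.int(3L, total, replace = TRUE) - 1L          # 0,1,2 = sky/building/road
  if (n_green > 0) {
    green_pos <- sample.int(total, n_green)
    cls[green_pos] <- sample(3:5, n_green, replace = TRUE)   # 3,4,5 = tree/grass/shrub
  }
  pal <- default_palette()
  views <- lapply(seq_len(n_views), function(v) {
    m <- matrix(cls[((v - 1) * h * w + 1):(v * h * w)], nrow = h, ncol = w)
    label_image(m, palette = pal)
  })
  names(views) <- as.character((seq_len(n_views) - 1L) * (360 %/% n_views))
  views
}

#' Default pixel-class palette for synthetic label images
#'
#' @return Named character vector mapping class id to semantic name.
#' @export
default_palette <- function() {
  c(`0` = "sky", `1` = "building", `2` = "road",
    `3` = "tree", `4` = "grass", `5` = "shrub")
}

#' Tessellate the extent into non-overlapping community polygons
#'
#' Recursive seeded binary space partition: the largest remaining rectangle
#' is split at a random position along its longer side until \code{n}
#' rectangles exist. The cells are convex, pairwise interior-disjoint, and
#' exactly tile the extent.
#'
#' @param extent_m study extent \code{c(xmin, ymin, xmax, ymax)}.
#' @param n number of communities, >= 1.
#' @param seed integer RNG seed.
#' @param min_side_m smallest allowed cell side; splitting stops (with an
#'   error) if \code{n} cells cannot be formed without thinner slivers.
#' @return List of \code{n} polygon matrices (4 x 2, open ring), named
#'   "1".."n".
#' @export
generate_communities <- function(extent_m, n, seed = 1L, min_side_m = 1) {
  stopifnot(length(extent_m) == 4)
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  rects <- list(as.numeric(extent_m))  # each c(xmin, ymin, xmax, ymax)
  while (length(rects) < n) {
    areas <- vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0)
    i <- which.max(areas)
    r <- rects[[i]]
    w <- r[3] - r[1]; h <- r[4] - r[2]
    if (max(w, h) < 2 * min_side_m) {
      stop(sprintf("cannot tessellate extent into %d cells with min side %g m", n, min_side_m))
    }
    f <- stats::runif(1, 0.35, 0.65)
    if (w >= h) {
      cut <- r[1] + f * w
      new <- list(c(r[1], r[2], cut, r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[2] + f * h
      new <- list(c(r[1], r[2], r[3], cut), c(r[1], cut, r[3], r[4]))
    }
    rects[[i]] <- new[[1]]
    rects[[length(rects) + 1L]] <- new[[2]]
  }
  polys <- lapply(rects, function(r) {
    rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4]))
  })
  names(polys) <- as.character(seq_len(n))
  polys
}

#' Generate community rental prices with a planted spatial association
#'
#' price_i = alpha + beta * (W gvi)_i + eps_i with eps ~ Normal(0, sigma^2),
#' floored at a positive minimum (the inequity statistic divides by price).
#' beta < 0 plants a negative price-greenness association (wealthier
#' communities in less green surroundings), beta > 0 the opposite, beta = 0
#' the null.
#'
#' @param gvi numeric vector of community greenness values.
#' @param weights a row-standardized \code{\link{spatial_weights}} object.
#' @param alpha intercept, currency/m^2.
#' @param beta slope, currency/m^2 per unit of spatially lagged GVI.
#' @param sigma noise standard deviation, currency/m^2.
#' @param seed integer RNG seed.
#' @param floor minimum price after noise, currency/m^2 (> 0).
#' @return Numeric price vector, same length as \code{gvi}.
#' @export
generate_prices <- function(gvi, weights, alpha = 40, beta = -30, sigma = 5,
                            seed = 1L, floor = 1) {
  if (!inherits(weights, "spatial_weights")) stop("weights must be a spatial_weights object")
  if (weights$n != length(gvi)) {
    stop(sprintf("dimension mismatch: %d weights rows vs %d gvi values", weights$n, length(gvi)))
  }
  if (!all(is.finite(gvi))) stop("gvi values must be finite")
  if (!isTRUE(weights$row_standardized)) stop("weights must be row-standardized")
  if (floor <= 0) stop("price floor must be positive")
  set.seed(as.integer(seed))
  lag <- spatial_lag(weights, gvi)
  pmax(alpha + beta * lag + stats::rnorm(length(gvi), 0, sigma), floor)
}
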