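test_that("street grid line counts follow the spacing arithmetic", {
  ext <- c(0, 0, 1000, 1000)
  g1 <- generate_street_grid(ext, 500, jitter = 0, seed = 1)
  expect_length(g1$segments, 6)  # 3 horizontal + 3 vertical at 0, 500, 1000
  g2 <- generate_street_grid(ext, 200, jitter = 0, seed = 1)
  expect_length(g2$segments, 12)
  expect_error(generate_street_grid(ext, 0), "positive")
  expect_error(generate_street_grid(ext, 1200), "smaller")
})

test_that("street grid is deterministic under a seed and vertices stay in the extent", {
  ext <- c(0, 0, 2000, 1500)
  a <- generate_street_grid(ext, 250, jitter = 0.2, seed = 7)
  b <- generate_street_grid(ext, 250, jitter = 0.2, seed = 7)
  expect_identical(a, b)
  allv <- do.call(rbind, a$segments)
  expect_true(all(allv[, 1] >= ext[1] & allv[, 1] <= ext[3]))
  expect_true(all(allv[, 2] >= ext[2] & allv[, 2] <= ext[4]))
  # every segment has positive length
  expect_true(all(vapply(a$segments, function(s) sum(sqrt(rowSums(diff(s)^2))), 0) > 0))
})

test_that("sample points follow arc-length arithmetic and dedup intersections", {
  street <- structure(list(segments = list(cbind(c(0, 1000), c(0, 0))),
                           extent = c(0, 0, 1000, 10)), class = "street_network")
  expect_equal(sample_points(street, 200)$x, seq(0, 1000, 200))
  expect_equal(nrow(sample_points(street, 50)), 21)
  # two crossing streets sharing the midpoint: crossing emitted once
  cross <- structure(list(segments = list(cbind(c(0, 1000), c(500, 500)),
                                          cbind(c(500, 500), c(0, 1000))),
                          extent = c(0, 0, 1000, 1000)), class = "street_network")
  pts <- sample_points(cross, 250)
  expect_equal(sum(pts$x == 500 & pts$y == 500), 1)
  expect_equal(nrow(pts), 9)
  # empty network
  empty <- structure(list(segments = list(), extent = c(0, 0, 1, 1)),
                     class = "street_network")
  expect_equal(nrow(sample_points(empty, 10)), 0)
})

test_that("planted green field honors trend, clipping, and determinism", {
  ext <- c(0, 0, 1000, 1000)
  const <- plant_green_field(ext, trend = c(0.4, 0, 0), noise_sd = 0)
  expect_equal(const$eval(c(10, 500, 990), c(5, 900, 20)), rep(0.4, 3))
  dec <- plant_green_field(ext, trend = c(0.8, -0.001, 0), noise_sd = 0)
  xs <- seq(0, 1000, 100)
  expect_true(all(diff(dec$eval(xs, rep(500, length(xs)))) <= 0))
  # clipped to [0, 1]
  wild <- plant_green_field(ext, trend = c(2, -0.005, 0), noise_sd = 0.5, seed = 3)
  v <- wild$eval(runif(200, 0, 1000), runif(200, 0, 1000))
  expect_true(all(v >= 0 & v <= 1))
  f1 <- plant_green_field(ext, trend = c(0.3, 0, 0), noise_sd = 0.1, seed = 11)
  f2 <- plant_green_field(ext, trend = c(0.3, 0, 0), noise_sd = 0.1, seed = 11)
  expect_identical(f1$eval(1:10, 10:1), f2$eval(1:10, 10:1))
})

test_that("rendered views hit the pooled green count exactly", {
  for (f in c(0, 0.25, 0.5, 1)) {
    v <- render_views(f, c(100, 100), 4, seed = 5)
    pooled <- sum(vapply(v, function(i) green_fraction(i)[1], 0))
    expect_identical(pooled, round(f * 4 * 100 * 100))
  }
  expect_error(render_views(1.2, c(10, 10)), "\\[0, 1\\]")
  expect_error(render_views(-0.1, c(10, 10)), "\\[0, 1\\]")
})

test_that("community tessellation is disjoint, area-conserving, deterministic", {
  ext <- c(0, 0, 1000, 800)
  one <- generate_communities(ext, 1)
  expect_length(one, 1)
  expect_equal(polygon_area(one[[1]]), 1000 * 800)
  polys <- generate_communities(ext, 40, seed = 9)
  expect_length(polys, 40)
  areas <- vapply(polys, polygon_area, 0)
  expect_true(all(areas > 0))
  expect_equal(sum(areas), 1000 * 800)  # exact tiling
  # pairwise interior disjoint: centroids of each cell lie in no other cell
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  for (i in seq_along(polys)) {
    others <- setdiff(seq_along(polys), i)
    hits <- vapply(others, function(j) point_in_polygon(cents[i, 1], cents[i, 2], polys[[j]]), NA)
    expect_false(any(hits))
  }
  expect_identical(generate_communities(ext, 40, seed = 9), polys)
  expect_error(generate_communities(ext, 0), ">= 1")
  expect_error(generate_communities(c(0, 0, 4, 4), 100, min_side_m = 1), "cannot tessellate")
})

test_that("price generator follows the planted linear model", {
  W <- path4_weights()
  gvi <- c(0.1, 0.3, 0.3, 0.1)
  # sigma = 0, beta = 0: all prices alpha
  expect_equal(generate_prices(gvi, W, alpha = 35, beta = 0, sigma = 0),
               rep(35, 4))
  # sigma = 0: exact linear arithmetic on the lag
  lag <- spatial_lag(W, gvi)
  expect_equal(generate_prices(gvi, W, alpha = 1000, beta = -1000, sigma = 0),
               1000 - 1000 * lag)
  # floor applies
  expect_equal(generate_prices(gvi, W, alpha = 0, beta = 0, sigma = 0, floor = 2),
               rep(2, 4))
  expect_error(generate_prices(c(0.1, 0.2), W, seed = 1), "dimension mismatch")
  W_raw <- spatial_weights(list(2L, 1L))
  expect_error(generate_prices(c(0.1, 0.2), W_raw), "row-standardized")
})

test_that("null price model (beta = 0) carries no association with the greenness lag", {
  n <- 50
  rw <- random_weights(n, standardized = TRUE)
  set.seed(99)
  gvi <- runif(n, 0.05, 0.5)
  lag <- spatial_lag(rw$W, gvi)
  cors <- vapply(seq_len(400), function(r) {
    p <- generate_prices(gvi, rw$W, alpha = 40, beta = 0, sigma = 10, seed = r)
    cor(p, lag)
  }, 0)
  # mean correlation within Monte-Carlo error of zero
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})
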