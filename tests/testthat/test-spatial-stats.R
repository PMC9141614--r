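test_that("queen contiguity matches the lattice definition", {
  g22 <- queen_weights(grid_polygons(2, 2))
  expect_true(all(vapply(g22$neighbors, length, 0L) == 3))  # rook edges + diagonal
  g33 <- queen_weights(grid_polygons(3, 3))
  expect_equal(length(g33$neighbors[[5]]), 8)               # center touches all
  expect_equal(sort(g33$neighbors[[1]]), c(2L, 4L, 5L))     # corner
  # symmetry
  for (i in 1:9) for (j in g33$neighbors[[i]]) expect_true(i %in% g33$neighbors[[j]])
  # disjoint distant squares are islands, with a warning
  far <- list(`1` = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
              `2` = rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11)),
              `3` = rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)))
  expect_warning(w <- queen_weights(far), "island")
  expect_equal(w$islands, 2L)
  expect_error(queen_weights(far[1]), "at least 2")
})

test_that("knn weights break ties by lower id and admit k = n-1", {
  pts <- cbind(c(0, 1, 3), c(0, 0, 0))
  w <- knn_weights(pts, 1)
  expect_equal(w$neighbors[[2]], 1L)  # nearer endpoint
  wc <- knn_weights(pts, 2)
  expect_true(all(vapply(wc$neighbors, length, 0L) == 2))  # complete graph
  # duplicate centroids: deterministic lower-id tie-break
  dup <- cbind(c(0, 0, 0), c(0, 0, 0))
  wd <- knn_weights(dup, 1)
  expect_equal(wd$neighbors[[1]], 2L)
  expect_equal(wd$neighbors[[2]], 1L)
  expect_equal(wd$neighbors[[3]], 1L)
  expect_error(knn_weights(pts, 0), "positive")
  expect_error(knn_weights(pts, 3), "smaller")
})

test_that("row standardization is idempotent and leaves islands at zero", {
  W <- spatial_weights(list(c(2L, 3L), 1L, 1L, integer()))
  R <- row_standardize(W)
  expect_equal(R$weights[[1]], c(0.5, 0.5))
  expect_true(R$row_standardized)
  expect_equal(row_standardize(R)$weights, R$weights)
  expect_equal(R$islands, 4L)
  expect_equal(spatial_lag(R, c(1, 2, 3, 4))[4], 0)
  expect_error(spatial_weights(list(1L), list(1)), "self-neighbors")
})

test_that("standardization uses the sample sd and is affine-invariant", {
  z <- standardize(c(1, 2, 3, 4))
  expect_equal(as.numeric(z), c(-1.161895, -0.387298, 0.387298, 1.161895),
               tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(3 * (1:4) + 10)), as.numeric(z))
  expect_error(standardize(rep(2, 5)), "constant")
  expect_error(standardize(1), "at least 2")
})

test_that("worked path-graph example: lag, global and local statistics", {
  W <- path4_weights()
  zP <- as.numeric(standardize(1:4))
  zA <- as.numeric(standardize(4:1))
  expect_equal(spatial_lag(W, zA), c(0.387298, 0.387298, -0.387298, -0.387298),
               tolerance = 1e-6)
  # row-standardized W, constant z: lag is the constant
  expect_equal(spatial_lag(W, rep(0.7, 4)), rep(0.7, 4))
  expect_equal(global_bivariate_moran(zP, zA, W), -0.4, tolerance = 1e-12)
  expect_equal(global_bivariate_moran(zP, zP, W), 0.4, tolerance = 1e-12)
  loc <- local_bivariate_moran(zP, zA, W)
  expect_equal(loc, c(-0.45, -0.15, -0.15, -0.45), tolerance = 1e-12)
  # local-to-global identity: N * sum(local) / ((N-1) * S0)
  expect_equal(4 * sum(loc) / (3 * W$S0), -0.4, tolerance = 1e-12)
  # sign flip is exact
  expect_equal(global_bivariate_moran(zP, -zA, W), 0.4, tolerance = 1e-12)
})

test_that("sparse statistics match the naive dense oracle on random instances", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    rw <- random_weights(n, standardized = (r %% 2 == 0))
    zP <- as.numeric(standardize(rnorm(n)))
    zA <- as.numeric(standardize(rnorm(n)))
    expect_equal(global_bivariate_moran(zP, zA, rw$W),
                 naive_global_moran(zP, zA, rw$M), tolerance = 1e-12)
    expect_equal(local_bivariate_moran(zP, zA, rw$W),
                 naive_local_moran(zP, zA, rw$M), tolerance = 1e-12)
    # A = P reduces to univariate Moran's I (formula-level cross-check)
    x <- rnorm(n)
    zx <- as.numeric(standardize(x))
    I_uni <- naive_univariate_moran(x, rw$M)
    expect_equal(global_bivariate_moran(zx, zx, rw$W), I_uni, tolerance = 1e-10)
  }
})

test_that("affine transforms of raw variables leave the permutation test invariant", {
  rw <- random_weights(30, standardized = TRUE)
  set.seed(5)
  P <- rnorm(30); A <- rnorm(30)
  r1 <- permutation_test_global(P, A, rw$W, n_perm = 99, seed = 3)
  r2 <- permutation_test_global(10 * P + 5, 2 * A - 1, rw$W, n_perm = 99, seed = 3)
  expect_equal(r1$I, r2$I, tolerance = 1e-12)
  expect_identical(r1$pseudo_p, r2$pseudo_p)
})

test_that("global permutation test: determinism and engineered extremes", {
  rw <- random_weights(60, standardized = TRUE)
  set.seed(6)
  P <- rnorm(60); A <- rnorm(60)
  a <- permutation_test_global(P, A, rw$W, n_perm = 199, seed = 42)
  b <- permutation_test_global(P, A, rw$W, n_perm = 199, seed = 42)
  expect_identical(a$pseudo_p, b$pseudo_p)
  expect_identical(a$perm_I, b$perm_I)
  expect_true(a$pseudo_p > 0 && a$pseudo_p <= 1)
  # perfectly engineered association: a smooth field against itself on a
  # large lattice; no permutation exceeds the observed statistic
  polys <- grid_polygons(8, 8)
  W <- row_standardize(queen_weights(polys))
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  smooth <- cents[, 1] + cents[, 2]
  res <- permutation_test_global(smooth, smooth, W, n_perm = 999, seed = 1)
  expect_equal(res$pseudo_p, 1 / 1000)
})

test_that("LISA quadrants follow the sign rule with High on ties", {
  expect_equal(moran_quadrant(c(1, 1, -1, -1, 0), c(1, -1, -1, 1, -2)),
               c("High-High", "High-Low", "Low-Low", "Low-High", "High-Low"))
})

test_that("conditional permutation LISA: labels partition, islands are NA, seeds reproduce", {
  polys <- grid_polygons(6, 6)
  W <- row_standardize(queen_weights(polys))
  set.seed(77)
  P <- rnorm(36); A <- rnorm(36)
  t1 <- conditional_permutation_local(P, A, W, n_perm = 199, seed = 9)
  t2 <- conditional_permutation_local(P, A, W, n_perm = 199, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 36)
  expect_true(all(t1$quadrant %in% c("High-High", "High-Low", "Low-Low", "Low-High")))
  expect_true(all(t1$pseudo_p > 0 & t1$pseudo_p <= 1))
  expect_equal(t1$local_I, t1$zP * t1$lag, tolerance = 1e-12)
  expect_equal(t1$significant, !is.na(t1$pseudo_p) & t1$pseudo_p <= 0.05)
  # island unit: zero local statistic, NA pseudo p
  Wi <- row_standardize(spatial_weights(list(2L, 1L, integer())))
  ti <- conditional_permutation_local(c(1, 2, 3), c(3, 1, 2), Wi, n_perm = 99, seed = 1)
  expect_equal(ti$local_I[3], 0)
  expect_true(is.na(ti$pseudo_p[3]))
})
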