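# Independent oracles and fixture builders shared across tests.

# Naive O(N^2) dense double-loop bivariate Moran's I; deliberately written
# from the formula with explicit loops, independent of the package's
# sparse-weights implementation.
naive_global_moran <- function(zP, zA, M) {
  n <- length(zP)
  s <- 0; S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        s <- s + M[i, j] * zP[i] * zA[j]
        S0 <- S0 + M[i, j]
      }
    }
  }
  n * s / ((n - 1) * S0)
}

naive_local_moran <- function(zP, zA, M) {
  n <- length(zP)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) if (j != i) acc <- acc + M[i, j] * zA[j]
    out[i] <- zP[i] * acc
  }
  out
}

# Univariate Moran's I from its own formula (cross-check for the A = P
# reduction).
naive_univariate_moran <- function(x, M) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        num <- num + M[i, j] * xc[i] * xc[j]
        S0 <- S0 + M[i, j]
      }
    }
  }
  (n / S0) * num / sum(xc^2)
}

# Random symmetric binary weights on n units (connected enough: resample
# until no empty matrix), optionally row-standardized; returns both the
# spatial_weights object and the dense matrix.
random_weights <- function(n, p = 0.15, standardized = FALSE) {
  repeat {
    M <- matrix(stats::rbinom(n * n, 1, p), n, n)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 0
    if (sum(M) > 0) break
  }
  nb <- lapply(seq_len(n), function(i) which(M[i, ] > 0))
  W <- spatial_weights(nb)
  if (standardized) {
    W <- row_standardize(W)
    M <- weights_matrix(W)
  }
  list(W = W, M = M)
}

# nx x ny lattice of unit squares (row-major ids), for queen-contiguity and
# calibration fixtures.
grid_polygons <- function(nx, ny, size = 1) {
  polys <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      x0 <- (ix - 1) * size; y0 <- (iy - 1) * size
      polys[[k]] <- rbind(c(x0, y0), c(x0 + size, y0),
                          c(x0 + size, y0 + size), c(x0, y0 + size))
    }
  }
  names(polys) <- as.character(seq_len(k))
  polys
}

# The 4-node path graph, row-standardized (the worked Moran example).
path4_weights <- function() {
  row_standardize(spatial_weights(list(2L, c(1L, 3L), c(2L, 4L), 3L)))
}

# A label image that is all one palette class.
uniform_label_image <- function(h, w, class_id = 3L) {
  label_image(matrix(as.integer(class_id), h, w), palette = default_palette())
}
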