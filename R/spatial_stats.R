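# Bivariate global and local Moran's I with permutation inference.
#
# Global statistic between a focal variable P (here rental price) and a
# context variable A (green exposure):
#
#   I_{P,A} = N * sum_i sum_{j != i} w_ij z_i^P z_j^A / ((N - 1) * S0)
#
# with z-scores using the sample (n-1) standard deviation and
# S0 = sum_ij w_ij. The local statistic is I'_i = z_i^P * sum_j w_ij z_j^A
# (the focal z times the spatial lag of the other variable), which satisfies
# N * sum_i I'_i / ((N - 1) * S0) = I exactly. Significance is assessed by
# permutation: the context variable is shuffled across units (conditionally
# on the focal unit for the local statistic), and the pseudo p-value is
# (1 + #{|I_perm| >= |I_obs|}) / (1 + n_perm).

#' Z-score standardization with sample standard deviation
#'
#' Uses the (n-1)-denominator sd, matching the (N-1) normalizer of the
#' global statistic. Constant input is an error: Moran's I is undefined.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Standardized vector with attributes \code{mean} and \code{sd}.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize")
  if (any(!is.finite(x))) stop("values must be finite")
  s <- stats::sd(x)
  if (s == 0) stop("constant variable; Moran's I undefined")
  structure((x - mean(x)) / s, mean = mean(x), sd = s)
}

#' Spatial lag
#'
#' lag_i = sum_j w_ij z_j. Island rows get lag 0.
#'
#' @param W a \code{\link{spatial_weights}} object.
#' @param z numeric vector of length \code{W$n}.
#' @return Numeric lag vector.
#' @export
spatial_lag <- function(W, z) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(z) != W$n) stop("dimension mismatch between weights and values")
  vapply(seq_len(W$n), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0) 0 else sum(W$weights[[i]] * z[nb])
  }, 0)
}

#' Global bivariate Moran's I
#'
#' @param zP standardized focal variable (e.g. rental price).
#' @param zA standardized context variable (e.g. green exposure).
#' @param W a \code{\link{spatial_weights}} object (S0 > 0).
#' @return The statistic I (scalar).
#' @export
global_bivariate_moran <- function(zP, zA, W) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- W$n
  if (length(zP) != n || length(zA) != n) stop("dimension mismatch")
  if (length(W$islands) == n) stop("all units are islands; S0 = 0")
  n * sum(zP * spatial_lag(W, zA)) / ((n - 1) * W$S0)
}

#' Local bivariate Moran's I
#'
#' local_I_i = z_i^P * sum_j w_ij z_j^A. Islands get 0. The values satisfy
#' the exact identity N * sum_i local_I_i / ((N-1) * S0) = global I.
#'
#' @inheritParams global_bivariate_moran
#' @return Numeric vector of local statistics.
#' @export
local_bivariate_moran <- function(zP, zA, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(zP) != W$n || length(zA) != W$n) stop("dimension mismatch")
  zP * spatial_lag(W, zA)
}

#' LISA quadrant from focal z-score and lag
#'
#' (+,+) High-High, (+,-) High-Low, (-,-) Low-Low, (-,+) Low-High; a z-score
#' or lag of exactly 0 classifies as "High" (>= 0 tie rule).
#'
#' @param zP focal z-scores.
#' @param lag spatial lag of the context z-scores.
#' @return Character vector of quadrant labels.
#' @export
moran_quadrant <- function(zP, lag) {
  p_hi <- zP >= 0; a_hi <- lag >= 0
  ifelse(p_hi & a_hi, "High-High",
         ifelse(p_hi & !a_hi, "High-Low",
                ifelse(!p_hi & !a_hi, "Low-Low", "Low-High")))
}

#' Permutation test for global bivariate Moran's I
#'
#' Holds P and W fixed and permutes A across units \code{n_perm} times.
#' Two-sided by default: pseudo_p = (1 + #{|I_perm| >= |I_obs|}) /
#' (1 + n_perm). One-sided alternatives compare signed statistics.
#'
#' @param P,A raw (unstandardized) variable vectors.
#' @param W a \code{\link{spatial_weights}} object.
#' @param n_perm number of permutations, default 999.
#' @param seed integer RNG seed (reported in the result).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return A \code{moran_global_result}: list(I, pseudo_p, n_perm, seed,
#'   alternative, S0, n, perm_I).
#' @export
permutation_test_global <- function(P, A, W, n_perm = 999L, seed = 1L,
                                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(W, "spatial_weights"), n_perm >= 1)
  zP <- as.numeric(standardize(P))
  zA <- as.numeric(standardize(A))
  n <- W$n
  M <- weights_matrix(W)
  scale <- n / ((n - 1) * W$S0)
  I_obs <- scale * sum(zP * (M %*% zA))
  set.seed(as.integer(seed))
  perm_idx <- vapply(seq_len(n_perm), function(p) sample.int(n), integer(n))
  Zperm <- matrix(zA[perm_idx], nrow = n)
  I_perm <- scale * colSums(zP * (M %*% Zperm))
  extreme <- switch(alternative,
                    two.sided = sum(abs(I_perm) >= abs(I_obs)),
                    greater   = sum(I_perm >= I_obs),
                    less      = sum(I_perm <= I_obs))
  structure(list(I = I_obs, pseudo_p = (1 + extreme) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alternative = alternative, S0 = W$S0, n = n, perm_I = I_perm),
            class = "moran_global_result")
}

#' @export
print.moran_global_result <- function(x, ...) {
  cat(sprintf("Global bivariate Moran's I = %.4f (n = %d, %d permutations, pseudo p = %.4f, %s)\n",
              x$I, x$n, x$n_perm, x$pseudo_p, x$alternative))
  invisible(x)
}

#' Conditional permutation test for local bivariate Moran's I (LISA)
#'
#' For each unit i the focal z_i^P is held fixed, the remaining context
#' z-scores are permuted and i's neighbors are drawn from the permuted pool,
#' \code{n_perm} times. Two-sided pseudo p per unit:
#' (1 + #{|local_perm| >= |local_obs|}) / (1 + n_perm). Quadrants are
#' assigned to every unit from (sign z_i^P, sign lag_i); the significance
#' flag subsets them at \code{alpha}. No multiplicity correction is applied
#' by default (the convention of standard LISA software); Benjamini-
#' Hochberg-adjusted p-values are returned alongside for an FDR filter.
#'
#' @inheritParams permutation_test_global
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame (one row per unit): zP, lag, local_I, quadrant,
#'   pseudo_p, p_fdr, significant. Island units get lag 0, local_I 0 and
#'   pseudo_p NA.
#' @export
conditional_permutation_local <- function(P, A, W, n_perm = 999L, seed = 1L,
                                          alpha = 0.05) {
  stopifnot(inherits(W, "spatial_weights"), n_perm >= 1)
  zP <- as.numeric(standardize(P))
  zA <- as.numeric(standardize(A))
  n <- W$n
  lag <- spatial_lag(W, zA)
  local_obs <- zP * lag
  set.seed(as.integer(seed))
  pseudo_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]
    k <- length(nb)
    if (k == 0) next
    pool <- zA[-i]
    wi <- W$weights[[i]]
    # n_perm draws of k values from the pool without replacement
    draws <- matrix(pool[vapply(seq_len(n_perm),
                                function(p) sample.int(n - 1L, k),
                                integer(k))],
                    nrow = k)
    lag_perm <- as.numeric(wi %*% draws)
    local_perm <- zP[i] * lag_perm
    pseudo_p[i] <- (1 + sum(abs(local_perm) >= abs(local_obs[i]))) / (1 + n_perm)
  }
  p_fdr <- stats::p.adjust(pseudo_p, method = "BH")
  data.frame(zP = zP, lag = lag, local_I = local_obs,
             quadrant = moran_quadrant(zP, lag),
             pseudo_p = pseudo_p, p_fdr = p_fdr,
             significant = !is.na(pseudo_p) & pseudo_p <= alpha)
}
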