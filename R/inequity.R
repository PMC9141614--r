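# Location-entropy (location quotient) inequity statistic and its
# seven-level summary.
#
# LQ_i = (GVI_i / price_i) / (sum_j GVI_j / sum_j price_j): the green space
# obtained per unit of rental price in community i, relative to the
# study-area-wide rate. LQ > 1 means above-average green service per unit of
# the income proxy. An exact algebraic consequence is that the
# price-weighted mean of LQ equals 1.

#' Location entropy (location quotient) of green exposure per unit price
#'
#' @param gvi community green exposure values (one buffer), length >= 2.
#' @param price community rental prices, currency/m^2, all > 0.
#' @param ids optional community ids used in error messages.
#' @return Numeric LQ vector (dimensionless, >= 0).
#' @export
location_entropy <- function(gvi, price, ids = seq_along(gvi)) {
  if (length(gvi) != length(price)) stop("gvi and price lengths differ")
  if (length(gvi) < 2) stop("location entropy needs at least 2 communities")
  bad <- which(!is.finite(price) | price <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive price for community %s", paste(ids[bad], collapse = ", ")))
  }
  if (any(!is.finite(gvi) | gvi < 0)) stop("gvi values must be finite and non-negative")
  if (sum(gvi) <= 0) stop("total GVI is zero; location entropy undefined")
  (gvi / price) / (sum(gvi) / sum(price))
}

#' Seven-level LQ bin labels
#'
#' @return Character vector of the seven bin labels, in order.
#' @export
lq_levels <- function() {
  c("<0.2", "0.2-0.5", "0.5-1.0", "1.0-1.5", "1.5-2.0", "2.0-5.0", ">5.0")
}

#' Bin LQ values into the seven levels
#'
#' Bins are half-open, lower-inclusive: [0, 0.2), [0.2, 0.5), [0.5, 1.0),
#' [1.0, 1.5), [1.5, 2.0), [2.0, 5.0), [5.0, Inf). So LQ = 1.0 falls in
#' "1.0-1.5" and LQ = 5.0 in ">5.0".
#'
#' @param lq numeric vector of LQ values (>= 0).
#' @return Factor with levels \code{\link{lq_levels}()}.
#' @export
bin_lq <- function(lq) {
  if (any(!is.finite(lq) | lq < 0)) stop("LQ values must be finite and non-negative")
  cut(lq, breaks = c(0, 0.2, 0.5, 1.0, 1.5, 2.0, 5.0, Inf),
      labels = lq_levels(), right = FALSE, include.lowest = TRUE)
}

#' Round half-up to a fixed number of decimals
#'
#' Ties away from zero at the last kept digit (0.125 -> 0.13 at 2 dp),
#' unlike base \code{round}'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Seven-level LQ summary with percentages
#'
#' Per-bin counts and percentages (100 * count / total, rounded half-up to
#' two decimals), plus the aggregate shares of the tails the inequity
#' reading focuses on: very low green service per unit price (LQ < 0.5,
#' below half the study-area average) and high (LQ > 2, more than twice the
#' average).
#'
#' @param lq numeric vector of LQ values (non-empty).
#' @return List with \code{table} (data.frame bin/count/percentage),
#'   \code{total}, \code{low} and \code{high} (each list(count, percentage);
#'   low is LQ < 0.5, high is LQ >= 2).
#' @export
lq_summary <- function(lq) {
  if (length(lq) == 0) stop("empty LQ vector")
  bins <- bin_lq(lq)
  counts <- as.integer(table(bins))
  total <- length(lq)
  tab <- data.frame(bin = lq_levels(), count = counts,
                    percentage = round_half_up(100 * counts / total, 2))
  low_n <- sum(counts[1:2]); high_n <- sum(counts[6:7])
  list(table = tab, total = total,
       low = list(count = low_n, percentage = round_half_up(100 * low_n / total, 2)),
       high = list(count = high_n, percentage = round_half_up(100 * high_n / total, 2)))
}
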