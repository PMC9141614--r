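# End-to-end reproducible run: simulate -> GVI -> exposure -> location
# entropy -> Moran/LISA, with one master seed, per-stage derived seeds, and
# a manifest. The default configuration is the package's synthetic study
# scale: a 12 km x 12 km city with a 200 m street grid sampled every 200 m
# (~7.4 thousand sample points), 499 communities, four 80 x 60 px views per
# point, and a price model planting a weak negative association between
# rental price and neighborhood greenness.

#' Pipeline configuration
#'
#' All knobs of the synthetic study in one validated list. Defaults are the
#' package's standard study conditions.
#'
#' @param extent_m study extent \code{c(xmin, ymin, xmax, ymax)}, meters.
#' @param street_spacing_m street grid spacing, meters.
#' @param street_jitter vertex jitter fraction of the spacing.
#' @param interval_m sampling interval along streets, meters.
#' @param image_shape label image size \code{c(H, W)} in pixels.
#' @param n_views views per sample point.
#' @param render_images if TRUE, per-point label images are rendered and GVI
#'   is computed from their pixels (round-quantized); if FALSE, the planted
#'   field value is used as the point GVI directly (fast path for large
#'   simulation studies — identical up to pixel quantization).
#' @param gvi_trend,gvi_length_scale,gvi_noise_sd,gvi_n_knots greenness
#'   field parameters (see \code{\link{plant_green_field}}). The default
#'   trend decreases from the old city (west) to the new districts (east).
#' @param n_communities number of community polygons.
#' @param price_alpha,price_beta,price_sigma,price_floor price model (see
#'   \code{\link{generate_prices}}); beta < 0 plants the negative
#'   price-greenness association.
#' @param price_buffer_minutes buffer whose community GVI drives the price
#'   model's spatial lag.
#' @param buffer_minutes walking-time grid for exposure.
#' @param walking_speed meters per minute.
#' @param exclusion_list point ids excluded by quality control.
#' @param min_views minimum views per kept point.
#' @param weights_type "queen" or "knn".
#' @param knn_k k for knn weights.
#' @param n_perm permutations for Moran inference.
#' @param alpha significance level for LISA flags.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A validated \code{run_config} list.
#' @export
city_config <- function(extent_m = c(0, 0, 12000, 12000),
                        street_spacing_m = 200, street_jitter = 0.15,
                        interval_m = 200,
                        image_shape = c(80L, 60L), n_views = 4L,
                        render_images = TRUE,
                        gvi_trend = NULL, gvi_length_scale = 1500,
                        gvi_noise_sd = 0.08, gvi_n_knots = 64L,
                        n_communities = 499L,
                        price_alpha = 40, price_beta = -30, price_sigma = 5,
                        price_floor = 1, price_buffer_minutes = 15,
                        buffer_minutes = c(5, 10, 15, 30), walking_speed = 72,
                        exclusion_list = integer(), min_views = 4L,
                        weights_type = c("queen", "knn"), knn_k = 6L,
                        n_perm = 999L, alpha = 0.05, seed = 1L) {
  weights_type <- match.arg(weights_type)
  if (is.null(gvi_trend)) {
    # greenness declining west -> east across the extent: from ~0.35 to ~0.15
    gvi_trend <- c(0.35, -0.2 / (extent_m[3] - extent_m[1]), 0)
  }
  cfg <- list(extent_m = extent_m, street_spacing_m = street_spacing_m,
              street_jitter = street_jitter, interval_m = interval_m,
              image_shape = as.integer(image_shape), n_views = as.integer(n_views),
              render_images = isTRUE(render_images),
              gvi_trend = gvi_trend, gvi_length_scale = gvi_length_scale,
              gvi_noise_sd = gvi_noise_sd, gvi_n_knots = as.integer(gvi_n_knots),
              n_communities = as.integer(n_communities),
              price_alpha = price_alpha, price_beta = price_beta,
              price_sigma = price_sigma, price_floor = price_floor,
              price_buffer_minutes = price_buffer_minutes,
              buffer_minutes = buffer_minutes, walking_speed = walking_speed,
              exclusion_list = exclusion_list, min_views = as.integer(min_views),
              weights_type = weights_type, knn_k = as.integer(knn_k),
              n_perm = as.integer(n_perm), alpha = alpha, seed = as.integer(seed))
  stopifnot(cfg$interval_m > 0, cfg$n_communities >= 1, cfg$n_perm >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$price_buffer_minutes %in% cfg$buffer_minutes)
  class(cfg) <- "run_config"
  cfg
}

#' Derive a stage seed from the master seed
#'
#' Deterministic and stable across platforms: a small hash of the stage
#' name mixed with the master seed, kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name string.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate the synthetic city
#'
#' Streets, sample points, greenness field, per-point GVI (rendered from
#' label images or taken from the field), communities, and prices planted
#' against the configured buffer's community GVI.
#'
#' @param config a \code{\link{city_config}}.
#' @return List: network, points (data.frame id/x/y/planted/green_count/
#'   total_count/gvi/qc_status), field, communities (polygon list),
#'   prices (data.frame id/price), exposure (community x buffer table),
#'   weights (row-standardized).
#' @export
simulate_city <- function(config) {
  stopifnot(inherits(config, "run_config"))
  net <- generate_street_grid(config$extent_m, config$street_spacing_m,
                              config$street_jitter, derive_seed(config$seed, "streets"))
  pts <- sample_points(net, config$interval_m)
  field <- plant_green_field(config$extent_m, config$gvi_trend,
                             config$gvi_length_scale, config$gvi_noise_sd,
                             config$gvi_n_knots, derive_seed(config$seed, "field"))
  pts$planted <- field$eval(pts$x, pts$y)
  npx <- config$n_views * prod(config$image_shape)
  if (config$render_images) {
    view_seed <- derive_seed(config$seed, "views")
    gvi <- numeric(nrow(pts))
    green_count <- integer(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      views <- render_views(pts$planted[i], config$image_shape,
                            config$n_views, view_seed + i)
      gvi[i] <- point_gvi(views)
      green_count[i] <- round(gvi[i] * npx)
    }
    pts$green_count <- green_count
    pts$total_count <- npx
    pts$gvi <- gvi
  } else {
    pts$green_count <- NA_integer_
    pts$total_count <- NA_integer_
    pts$gvi <- pts$planted
  }
  pts$qc_status <- ifelse(pts$id %in% config$exclusion_list, "excluded", "kept")
  pts$gvi[pts$qc_status == "excluded"] <- NA_real_
  comms <- generate_communities(config$extent_m, config$n_communities,
                                derive_seed(config$seed, "communities"))
  kept <- pts[pts$qc_status == "kept", ]
  expo <- exposure_table(comms, kept, config$buffer_minutes, config$walking_speed)
  W <- if (config$weights_type == "queen") {
    queen_weights(comms)
  } else {
    knn_weights(t(vapply(comms, polygon_centroid, numeric(2))), config$knn_k)
  }
  Wrs <- row_standardize(W)
  price_gvi <- expo$gvi[expo$minutes == config$price_buffer_minutes]
  if (anyNA(price_gvi)) {
    # communities with an empty price buffer get the area mean as the lag basis
    price_gvi[is.na(price_gvi)] <- mean(price_gvi, na.rm = TRUE)
  }
  prices <- generate_prices(price_gvi, Wrs, config$price_alpha, config$price_beta,
                            config$price_sigma, derive_seed(config$seed, "prices"),
                            config$price_floor)
  list(network = net, points = pts, field = field, communities = comms,
       prices = data.frame(id = names(comms), price = prices),
       exposure = expo, weights = Wrs)
}

#' Run the full exposure-inequity pipeline
#'
#' Simulates the city, then per walking-time buffer computes location
#' entropy with its seven-level summary and bivariate global/local Moran's I
#' between price and green exposure. Writes all stage outputs and a
#' manifest under \code{out_dir} when given; identical config and seed give
#' byte-identical outputs.
#'
#' @param config a \code{\link{city_config}}.
#' @param out_dir optional output directory (created if needed).
#' @return List: config, city, lq (long data.frame), lq_summaries (per
#'   buffer), moran_global (data.frame), lisa (long data.frame), manifest.
#' @export
run_pipeline <- function(config = city_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  city <- simulate_city(config)
  comm_ids <- names(city$communities)
  price <- city$prices$price

  lq_rows <- list(); lq_summaries <- list()
  mg_rows <- list(); lisa_rows <- list()
  n_missing <- integer(0)
  for (m in config$buffer_minutes) {
    sub <- city$exposure[city$exposure$minutes == m, ]
    sub <- sub[match(comm_ids, sub$community_id), ]
    ok <- !is.na(sub$gvi)
    n_missing[as.character(m)] <- sum(!ok)
    if (sum(!ok) > 0) {
      message(sprintf("buffer %d min: %d communit%s with no sample points excluded listwise",
                      m, sum(!ok), if (sum(!ok) == 1) "y" else "ies"))
    }
    lq <- location_entropy(sub$gvi[ok], price[ok], ids = comm_ids[ok])
    lq_rows[[as.character(m)]] <- data.frame(
      community_id = comm_ids[ok], minutes = m, lq = lq, bin = as.character(bin_lq(lq)))
    lq_summaries[[as.character(m)]] <- lq_summary(lq)

    if (sum(ok) == length(ok)) {
      W_m <- city$weights
    } else {
      # rebuild weights on the scored subset so Moran sees no missing units
      W_m <- row_standardize(queen_weights(city$communities[ok]))
    }
    g <- permutation_test_global(price[ok], sub$gvi[ok], W_m, config$n_perm,
                                 derive_seed(config$seed, paste0("moran", m)))
    mg_rows[[as.character(m)]] <- data.frame(
      minutes = m, radius_m = buffer_radius(m, config$walking_speed),
      I = g$I, pseudo_p = g$pseudo_p, n_perm = g$n_perm, seed = g$seed,
      n = g$n)
    li <- conditional_permutation_local(price[ok], sub$gvi[ok], W_m, config$n_perm,
                                        derive_seed(config$seed, paste0("lisa", m)),
                                        config$alpha)
    li <- cbind(community_id = comm_ids[ok], minutes = m, li)
    lisa_rows[[as.character(m)]] <- li
  }
  lq_df <- do.call(rbind, lq_rows); rownames(lq_df) <- NULL
  mg_df <- do.call(rbind, mg_rows); rownames(mg_df) <- NULL
  lisa_df <- do.call(rbind, lisa_rows); rownames(lisa_df) <- NULL

  manifest <- list(
    seed = config$seed,
    n_points_generated = nrow(city$points),
    n_points_kept = sum(city$points$qc_status == "kept"),
    n_points_excluded = sum(city$points$qc_status == "excluded"),
    n_communities = length(city$communities),
    n_missing_by_buffer = as.list(n_missing),
    buffer_minutes = config$buffer_minutes,
    n_perm = config$n_perm,
    weights_type = config$weights_type)

  result <- list(config = config, city = city, lq = lq_df,
                 lq_summaries = lq_summaries, moran_global = mg_df,
                 lisa = lisa_df, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' points.csv, communities.geojson, exposure.csv, lq.csv,
#' lq_summary.csv (seven-level table per buffer), moran_global.csv,
#' lisa.csv, manifest.json and config.json.
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param out_dir output directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_table_csv(result$city$points[, c("id", "x", "y", "green_count",
                                         "total_count", "gvi", "qc_status")],
                  p("points.csv"))
  write_communities_geojson(result$city$communities, result$city$prices,
                            p("communities.geojson"))
  write_table_csv(result$city$exposure, p("exposure.csv"))
  write_table_csv(result$lq, p("lq.csv"))
  sumtab <- do.call(rbind, lapply(names(result$lq_summaries), function(m) {
    s <- result$lq_summaries[[m]]
    cbind(minutes = as.numeric(m), s$table)
  }))
  write_table_csv(sumtab, p("lq_summary.csv"))
  write_table_csv(result$moran_global, p("moran_global.csv"))
  write_table_csv(result$lisa, p("lisa.csv"))
  jsonlite::write_json(result$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- result$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
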