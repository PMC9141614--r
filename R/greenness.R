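# Green View Index (GVI) from per-point street-view label images.
#
# The GVI of a sample point is the pooled fraction of vegetation pixels over
# its (up to four) cardinal-direction views: ratio of summed green counts to
# summed totals, not the mean of per-image ratios. For equal-sized views the
# two coincide; for unequal sizes the ratio of sums is used.
#
# Semantic segmentation itself is out of scope: the contract is "label
# images in, GVI out". Label rasters from any segmenter are ingested
# directly; a rule-based HSV color classifier is provided so the pipeline is
# exercisable end to end on RGB images without a trained model.

#' Construct a label image
#'
#' @param classes integer matrix (H x W) of pixel class ids.
#' @param palette named character vector mapping class id (name) to semantic
#'   class name, e.g. \code{c(`0` = "sky", `3` = "tree")}.
#' @param green_classes character vector of palette names counted as
#'   vegetation (case-insensitive). Default: grass, trees and shrubs.
#' @return A \code{label_image} object.
#' @export
label_image <- function(classes, palette,
                        green_classes = c("tree", "grass", "shrub")) {
  if (!is.matrix(classes)) stop("classes must be a matrix of class ids")
  if (length(classes) == 0) stop("label image must have at least one pixel")
  storage.mode(classes) <- "integer"
  if (is.null(names(palette)) || any(names(palette) == "")) {
    stop("palette must be a named vector (names are class ids)")
  }
  present <- unique(as.vector(classes))
  unknown <- setdiff(present, as.integer(names(palette)))
  if (length(unknown) > 0) {
    stop(sprintf("raster values not in palette: %s", paste(unknown, collapse = ", ")))
  }
  structure(list(classes = classes, palette = palette,
                 green_classes = tolower(green_classes)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  gc_ <- green_fraction(x)
  cat(sprintf("label_image %d x %d px, %d classes, green %d/%d (%.3f)\n",
              nrow(x$classes), ncol(x$classes), length(x$palette),
              gc_[1], gc_[2], gc_[1] / gc_[2]))
  invisible(x)
}

#' Rule-based green-pixel classifier for RGB images
#'
#' Classifies a pixel as vegetation when its hue lies in the configured
#' green band and its saturation and value exceed thresholds (gray or very
#' dark pixels are never green). A deterministic stand-in for a semantic
#' segmentation model, adequate for constructed fixtures and synthetic
#' imagery; it is not a substitute for segmentation quality on photographs.
#'
#' @param rgb numeric array H x W x 3, values in [0, 1] or [0, 255].
#' @param hue_range green hue band in degrees (default 60-180, pure green =
#'   120).
#' @param min_saturation,min_value HSV thresholds in [0, 1].
#' @return A binary \code{\link{label_image}} with palette
#'   \code{c(`0` = "background", `1` = "green")}.
#' @export
classify_green <- function(rgb, hue_range = c(60, 180),
                           min_saturation = 0.15, min_value = 0.1) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("classify_green expects a 3-channel (H x W x 3) RGB image")
  }
  mx <- max(rgb)
  maxc <- if (mx > 1) 255 else 1
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  flat <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = maxc)
  hue <- hsv[1, ] * 360
  green <- hue >= hue_range[1] & hue <= hue_range[2] &
    hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  label_image(matrix(as.integer(green), nrow = h, ncol = w),
              palette = c(`0` = "background", `1` = "green"),
              green_classes = "green")
}

#' Green and total pixel counts of a label image
#'
#' @param img a \code{\link{label_image}}.
#' @return Integer vector \code{c(green_count, total_count)}.
#' @export
green_fraction <- function(img) {
  stopifnot(inherits(img, "label_image"))
  green_ids <- as.integer(names(img$palette)[tolower(img$palette) %in% img$green_classes])
  c(green_count = sum(img$classes %in% green_ids),
    total_count = length(img$classes))
}

#' Green View Index of a sample point
#'
#' Pools the views of one sample point: GVI = (sum of green pixel counts) /
#' (sum of total pixel counts). For equal-sized views this equals the mean
#' of the per-view green fractions; for unequal sizes the ratio of sums is
#' the defining form.
#'
#' @param views list of \code{\link{label_image}} objects (>= 1).
#' @return GVI fraction in [0, 1].
#' @export
point_gvi <- function(views) {
  if (length(views) < 1) stop("point_gvi requires at least one view")
  counts <- vapply(views, green_fraction, c(green_count = 0, total_count = 0))
  tot <- sum(counts["total_count", ])
  if (tot == 0) stop("zero total pixels across views")
  sum(counts["green_count", ]) / tot
}

#' Quality control for sample points
#'
#' Mechanizes the study design's visual screening of non-green-season
#' imagery as an explicit exclusion list: a point is excluded iff its id is
#' listed or it has fewer than \code{min_views} views. Excluded points carry
#' no GVI and are omitted from all downstream stages.
#'
#' @param points list of sample points, each a list with at least \code{id}
#'   and \code{views} (list of \code{\link{label_image}}).
#' @param exclusion_list vector of point ids to exclude.
#' @param min_views minimum required number of views (default 4).
#' @return The same list with \code{qc_status} ("kept"/"excluded") set and
#'   \code{gvi} computed for kept points.
#' @export
apply_qc <- function(points, exclusion_list = integer(), min_views = 4L) {
  lapply(points, function(p) {
    excluded <- p$id %in% exclusion_list || length(p$views) < min_views
    p$qc_status <- if (excluded) "excluded" else "kept"
    p$gvi <- if (excluded) NA_real_ else point_gvi(p$views)
    p
  })
}

#' Tabulate QC'd sample points
#'
#' @param points list of sample points after \code{\link{apply_qc}}; each
#'   carries \code{id}, \code{x}, \code{y}, \code{views}, \code{gvi},
#'   \code{qc_status}.
#' @return data.frame with columns id, x, y, green_count, total_count, gvi,
#'   qc_status (counts NA for excluded points).
#' @export
points_table <- function(points) {
  rows <- lapply(points, function(p) {
    if (identical(p$qc_status, "kept")) {
      counts <- vapply(p$views, green_fraction, c(green_count = 0, total_count = 0))
      g <- sum(counts["green_count", ]); t <- sum(counts["total_count", ])
    } else {
      g <- NA_integer_; t <- NA_integer_
    }
    data.frame(id = p$id, x = p$x, y = p$y, green_count = g, total_count = t,
               gvi = if (is.null(p$gvi)) NA_real_ else p$gvi,
               qc_status = p$qc_status)
  })
  do.call(rbind, rows)
}

#' Write a label image as a PNG class raster with a JSON palette sidecar
#'
#' The PNG stores class ids in a single gray channel (id/255); the sidecar
#' records the palette and green classes so the raster round-trips exactly.
#'
#' @param img a \code{\link{label_image}}.
#' @param path output PNG path; the sidecar is written to
#'   \code{paste0(path, ".palette.json")} unless \code{palette_path} given.
#' @param palette_path optional sidecar path.
#' @return \code{path}, invisibly.
#' @export
write_label_image <- function(img, path, palette_path = paste0(path, ".palette.json")) {
  stopifnot(inherits(img, "label_image"))
  if (max(img$classes) > 255) stop("class ids above 255 cannot be stored in 8-bit PNG")
  png::writePNG(img$classes / 255, target = path)
  jsonlite::write_json(list(palette = as.list(img$palette),
                            green_classes = img$green_classes),
                       palette_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PNG class raster with its JSON palette sidecar
#'
#' @param path PNG path.
#' @param palette_path sidecar path (default \code{paste0(path,
#'   ".palette.json")}).
#' @return A \code{\link{label_image}}.
#' @export
read_label_image <- function(path, palette_path = paste0(path, ".palette.json")) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  meta <- jsonlite::read_json(palette_path, simplifyVector = TRUE)
  label_image(matrix(as.integer(round(raw * 255)), nrow = nrow(raw)),
              palette = unlist(meta$palette),
              green_classes = meta$green_classes)
}
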