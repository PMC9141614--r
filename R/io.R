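# Read/write adapters: community GeoJSON FeatureCollections and CSV tables.
# Coordinates are projected planar meters; the CRS name is recorded in a
# foreign "crs" member of the FeatureCollection. Built on jsonlite; lossless
# for the Polygon feature sets the pipeline emits.

#' Write communities to a GeoJSON FeatureCollection
#'
#' One Polygon feature per community with its attributes as properties.
#'
#' @param polygons named list of polygon matrices (n x 2, open rings).
#' @param properties data.frame of per-community attributes; must contain
#'   \code{id} matching \code{names(polygons)} (coerced to character).
#' @param path output path.
#' @param crs_name free-text CRS note (default "projected-meters").
#' @return \code{path}, invisibly.
#' @export
write_communities_geojson <- function(polygons, properties, path,
                                      crs_name = "projected-meters") {
  stopifnot("id" %in% names(properties), length(polygons) == nrow(properties))
  ids <- as.character(properties$id)
  if (!identical(names(polygons), ids)) polygons <- polygons[ids]
  features <- lapply(seq_along(polygons), function(i) {
    ring <- rbind(polygons[[i]], polygons[[i]][1, ])  # GeoJSON rings are closed
    props <- as.list(properties[i, , drop = FALSE])
    props$id <- ids[i]
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  obj <- list(type = "FeatureCollection", crs = crs_name, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read communities from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON path written by \code{\link{write_communities_geojson}}
#'   or any FeatureCollection of Polygon features with an \code{id} property.
#' @return List with \code{polygons} (named list of matrices),
#'   \code{properties} (data.frame) and \code{crs}.
#' @export
read_communities_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) stop("not a GeoJSON FeatureCollection")
  feats <- obj$features
  polygons <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon")) {
      stop(sprintf("feature %d: missing or non-Polygon geometry", i))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) as.numeric(unlist(xy))))
    if (ncol(m) != 2 || nrow(m) < 4) stop(sprintf("feature %d: malformed ring", i))
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polygons[[i]] <- m
    props[[i]] <- as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                                stringsAsFactors = FALSE)
  }
  properties <- do.call(rbind, props)
  if (is.null(properties$id)) stop("features carry no 'id' property")
  names(polygons) <- as.character(properties$id)
  list(polygons = polygons, properties = properties,
       crs = if (is.null(obj$crs)) NA_character_ else obj$crs)
}

#' Write a pipeline CSV (missing values as empty fields)
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline CSV
#'
#' Extra columns beyond \code{required} are preserved with a warning.
#'
#' @param path CSV path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table_csv <- function(path, required = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing column(s) in %s: %s", path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(required) > 0 && length(extra) > 0) {
    warning(sprintf("extra column(s) preserved: %s", paste(extra, collapse = ", ")))
  }
  df
}
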