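# CSV and GeoJSON input/output for areas and access results.

#' Read an area or facility table from CSV
#'
#' Plain `utf-8` CSV with one header row; coordinates in WGS84 decimal
#' degrees. Basic coordinate validity is checked.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_geo_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("lon", "lat") %in% names(x))) {
    if (any(abs(x$lat) > 90) || any(x$lon < -180 | x$lon >= 180))
      stop("invalid coordinates in ", path)
  }
  x
}

#' Write per-area access results as a GeoJSON FeatureCollection
#'
#' One Point feature per area at its population-weighted centroid, with the
#' access-table fields as properties. Written with WGS84 coordinates as
#' GeoJSON requires.
#'
#' @param access Result of [access_table()].
#' @param areas Area table providing `area_id`, `lon`, `lat`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_access_geojson <- function(access, areas, path) {
  i <- match(access$area_id, areas$area_id)
  if (any(is.na(i))) stop("areas table does not cover all access rows")
  features <- lapply(seq_len(nrow(access)), function(r) {
    props <- as.list(access[r, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(areas$lon[i[r]], areas$lat[i[r]])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
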