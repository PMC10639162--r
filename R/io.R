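#' Write district centroids as GeoJSON points
#'
#' Emits a `FeatureCollection` of `Point` features with `district_id` and
#' `population` properties and `[u, v]` planar coordinates.
#'
#' @param districts data frame with `district_id`, `u`, `v`, `population`.
#' @param path output file path.
#' @param properties extra per-district property columns to carry along
#'   (named columns of `districts`).
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(districts, path, properties = "population") {
  stopifnot(all(c("district_id", "u", "v") %in% names(districts)),
            all(properties %in% names(districts)))
  feats <- lapply(seq_len(nrow(districts)), function(i) {
    props <- c(list(district_id = districts$district_id[i]),
               lapply(districts[i, properties, drop = FALSE], identity))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(districts$u[i], districts$v[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read district centroids from GeoJSON points
#'
#' @param path a GeoJSON file written by [write_geojson_points()] (or any
#'   Point FeatureCollection with `district_id` properties).
#' @return Data frame with `district_id`, `u`, `v` and any scalar properties.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Point"))
    cc <- unlist(f$geometry$coordinates)
    c(list(u = cc[1], v = cc[2]), f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df[, c("district_id", setdiff(names(df), "district_id")), drop = FALSE]
}

# CSV writer with fixed conventions so repeated runs are byte-identical
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
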