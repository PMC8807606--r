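# Plain-text serialization. Gridded fields go to a JSON layout carrying the
# coordinate vectors (with units attributes), the monthly time axis, the
# units/name metadata and the value cube with nulls for missing cells; tables
# go to CSV. The layout mirrors the (time, lat, lon) dimension convention of
# the NetCDF files the pipeline would consume in production.

#' Write a grid field to a JSON file
#'
#' @param field A [grid_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  g <- field$geometry
  obj <- list(type = "grid_field",
              name = field$name, units = field$units,
              lat = list(values = g$lat, units = "degrees_north"),
              lon = list(values = g$lon, units = "degrees_east",
                         convention = g$lon_convention),
              time = list(year = field$time$year, month = field$time$month),
              dims = c("time", "lat", "lon"),
              values = field$values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a grid field written by [write_grid_field()]
#' @param path JSON file path.
#' @return A [grid_field()].
#' @export
read_grid_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "grid_field"))
    stop("read_grid_field: not a grid field file")
  geom <- grid_geometry(obj$lat$values, obj$lon$values,
                        lon_convention = obj$lon$convention)
  vals <- obj$values
  if (!is.array(vals) || length(dim(vals)) != 3L)
    vals <- array(unlist(vals),
                  c(length(obj$time$year), length(geom$lat),
                    length(geom$lon)))
  grid_field(vals, geom,
             data.frame(year = obj$time$year, month = obj$time$month),
             units = obj$units, name = obj$name)
}

#' Write a climate-zone map to a JSON file
#' @param zones A [climate_zone_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climate_zones <- function(zones, path) {
  stopifnot(inherits(zones, "climate_zone_map"))
  g <- zones$geometry
  obj <- list(type = "climate_zone_map",
              lat = list(values = g$lat, units = "degrees_north"),
              lon = list(values = g$lon, units = "degrees_east",
                         convention = g$lon_convention),
              codes = c("0" = "non-land", stats::setNames(zones$levels, 1:5)),
              zone = zones$zone)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a climate-zone map written by [write_climate_zones()]
#' @param path JSON file path.
#' @return A [climate_zone_map()].
#' @export
read_climate_zones <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "climate_zone_map"))
    stop("read_climate_zones: not a climate zone file")
  geom <- grid_geometry(obj$lat$values, obj$lon$values,
                        lon_convention = obj$lon$convention)
  climate_zone_map(geom, matrix(obj$zone, length(geom$lat),
                                length(geom$lon)))
}

#' Write decomposition records or sensitivity samples to CSV
#' @param records A data frame / data.table of records or samples.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

#' Read a records/samples CSV written by [write_records_csv()]
#' @param path CSV path.
#' @return A `data.table`.
#' @export
read_records_csv <- function(path) {
  data.table::fread(path)
}
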