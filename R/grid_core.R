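#' Grid geometry for a regular latitude/longitude raster
#'
#' Cell-center registered geometry. Spacing must be regular in each dimension
#' (within 1e-9 degrees); one longitude convention per dataset, either
#' `"pm180"` (longitudes in \[-180, 180)) or `"0360"` (\[0, 360)).
#'
#' @param lat Numeric vector of latitude centers, degrees north, strictly
#'   monotone increasing, within \[-90, 90\].
#' @param lon Numeric vector of longitude centers, degrees east, strictly
#'   monotone increasing, regular spacing.
#' @param lon_convention `"pm180"` or `"0360"`.
#' @return An object of class `grid_geometry` with fields `lat`, `lon`,
#'   `lon_convention`, and the implied spacings `dlat`, `dlon`.
#' @export
grid_geometry <- function(lat, lon, lon_convention = c("pm180", "0360")) {
  lon_convention <- match.arg(lon_convention)
  if (length(lat) < 1L || length(lon) < 1L)
    stop("grid_geometry: empty coordinate vector")
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("grid_geometry: non-finite coordinates")
  if (any(lat < -90 | lat > 90))
    stop("grid_geometry: latitude outside [-90, 90]")
  rng <- if (lon_convention == "pm180") c(-180, 180) else c(0, 360)
  if (any(lon < rng[1] | lon >= rng[2]))
    stop("grid_geometry: longitude outside ", rng[1], "..", rng[2])
  check_regular <- function(x, what) {
    if (length(x) == 1L) return(NA_real_)
    d <- diff(x)
    if (any(d <= 0)) stop("grid_geometry: ", what, " not strictly increasing")
    if (max(d) - min(d) > 1e-9)
      stop("grid_geometry: irregular ", what, " spacing")
    d[1]
  }
  dlat <- check_regular(lat, "latitude")
  dlon <- check_regular(lon, "longitude")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 lon_convention = lon_convention,
                 dlat = dlat, dlon = dlon),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d lat x %d lon, lat %.3f..%.3f, lon %.3f..%.3f (%s)\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon), x$lon_convention))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= tol && max(abs(a$lon - b$lon)) <= tol
}

#' A physical variable on a regular lat/lon grid with a monthly time axis
#'
#' `values` is a numeric array `[time, lat, lon]`; missing data are `NA`.
#' Units must be non-empty for physical variables.
#'
#' @param values Numeric array `[n_time, n_lat, n_lon]` (a matrix
#'   `[n_lat, n_lon]` is accepted for a single time step).
#' @param geometry A [grid_geometry()].
#' @param time Data frame with integer columns `year` and `month` (1-12), one
#'   row per time step.
#' @param units Units string (e.g. `"degC"`, `"m2/m2"`, `"%"`, `"W/m2"`,
#'   `"mm/day"`).
#' @param name Variable name.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, geometry, time, units, name = "") {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (length(dim(values)) != 3L)
    stop("grid_field: values must be [time, lat, lon]")
  if (is.null(time)) time <- data.frame(year = 0L, month = 1L)
  time <- as.data.frame(time)
  if (!all(c("year", "month") %in% names(time)))
    stop("grid_field: time needs 'year' and 'month' columns")
  if (any(time$month < 1L | time$month > 12L))
    stop("grid_field: month outside 1..12")
  d <- dim(values)
  if (d[1] != nrow(time) || d[2] != length(geometry$lat) ||
      d[3] != length(geometry$lon))
    stop("grid_field: values dims [", paste(d, collapse = ","),
         "] do not match time/geometry")
  if (any(is.infinite(values)))
    stop("grid_field: infinite values; use NA for missing data")
  if (!nzchar(units)) stop("grid_field: units must be non-empty")
  structure(list(values = values, geometry = geometry, time = time,
                 units = units, name = name),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> '%s' [%s], %d time x %d lat x %d lon, %.1f%% missing\n",
              x$name, x$units, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3], 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Extract one time slice of a grid field as a lat x lon matrix
#' @param field A [grid_field()].
#' @param t Time index.
#' @return Numeric matrix `[lat, lon]`.
#' @export
field_slice <- function(field, t) {
  stopifnot(inherits(field, "grid_field"))
  nt <- dim(field$values)[1]
  if (t < 1L || t > nt) stop("field_slice: time index out of range")
  field$values[t, , , drop = TRUE]
}

#' Cosine-latitude cell area weights
#'
#' On a regular lat/lon grid the cell area is proportional to cos(latitude);
#' these weights stand in for the per-cell areas in every area-weighted
#' statistic. Normalization is deferred to consumers.
#'
#' @param geometry A [grid_geometry()].
#' @return Object of class `area_weights` with `w`, a `[lat, lon]` matrix.
#' @export
cell_area_weights <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (any(abs(geometry$lat) > 90)) stop("cell_area_weights: invalid geometry")
  w_lat <- pmax(0, cos(geometry$lat * pi / 180))
  w <- matrix(w_lat, nrow = length(geometry$lat), ncol = length(geometry$lon))
  structure(list(geometry = geometry, w = w), class = "area_weights")
}

#' Area-weighted mean of one field slice over a mask
#'
#' @param x Numeric `[lat, lon]` matrix (NA = missing) or a single-time
#'   [grid_field()].
#' @param weights An [cell_area_weights()] object on the same geometry.
#' @param mask Optional logical `[lat, lon]` matrix restricting the domain.
#' @return Scalar weighted mean.
#' @export
area_weighted_mean <- function(x, weights, mask = NULL) {
  if (inherits(x, "grid_field")) {
    if (dim(x$values)[1] != 1L)
      stop("area_weighted_mean: pass a single time slice")
    x <- field_slice(x, 1L)
  }
  stopifnot(inherits(weights, "area_weights"))
  if (!all(dim(x) == dim(weights$w)))
    stop("area_weighted_mean: field/weights dimension mismatch")
  valid <- !is.na(x)
  if (!is.null(mask)) valid <- valid & mask
  valid <- valid & weights$w > 0
  if (!any(valid)) stop("area_weighted_mean: empty domain after masking")
  sum(weights$w[valid] * x[valid]) / sum(weights$w[valid])
}

#' Zonal (latitude-band) mean of a field slice
#'
#' Within one latitude row all cells share the same area weight, so the row
#' statistic is the mean over valid cells; rows with no valid cell are NA.
#'
#' @inheritParams area_weighted_mean
#' @return Numeric vector, one value per latitude row.
#' @export
zonal_mean <- function(x, weights = NULL) {
  if (inherits(x, "grid_field")) {
    if (dim(x$values)[1] != 1L)
      stop("zonal_mean: pass a single time slice")
    x <- field_slice(x, 1L)
  }
  rowMeans(x, na.rm = TRUE) -> out
  out[!is.finite(out)] <- NA_real_
  out
}

#' Bilinear regridding between regular lat/lon grids
#'
#' Standard bilinear interpolation in latitude/longitude; constants and planes
#' in (lat, lon) are reproduced exactly at target centers. A target point with
#' any missing source corner is missing (no imputation). Target centers must
#' lie within the source center hull.
#'
#' @param field A [grid_field()].
#' @param target A [grid_geometry()] inside the source hull.
#' @return A [grid_field()] on `target` with the same time axis.
#' @export
regrid_bilinear <- function(field, target) {
  stopifnot(inherits(field, "grid_field"), inherits(target, "grid_geometry"))
  src <- field$geometry
  if (min(target$lat) < min(src$lat) - 1e-9 ||
      max(target$lat) > max(src$lat) + 1e-9 ||
      min(target$lon) < min(src$lon) - 1e-9 ||
      max(target$lon) > max(src$lon) + 1e-9)
    stop("regrid_bilinear: target outside source hull")

  bracket <- function(xs, xt) {
    i0 <- findInterval(xt, xs, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(xs) - 1L)
    if (length(xs) == 1L) {
      list(lo = rep(1L, length(xt)), hi = rep(1L, length(xt)),
           f = rep(0, length(xt)))
    } else {
      f <- (xt - xs[i0]) / (xs[i0 + 1L] - xs[i0])
      list(lo = i0, hi = i0 + 1L, f = f)
    }
  }
  bi <- bracket(src$lat, target$lat)
  bj <- bracket(src$lon, target$lon)

  nt <- dim(field$values)[1]
  out <- array(NA_real_, c(nt, length(target$lat), length(target$lon)))
  wlat_lo <- 1 - bi$f; wlat_hi <- bi$f
  wlon_lo <- 1 - bj$f; wlon_hi <- bj$f
  for (t in seq_len(nt)) {
    z <- field$values[t, , , drop = TRUE]
    if (length(src$lat) == 1L) z <- matrix(z, nrow = 1L)
    if (length(src$lon) == 1L) z <- matrix(z, ncol = 1L)
    z11 <- z[bi$lo, bj$lo, drop = FALSE]; z21 <- z[bi$hi, bj$lo, drop = FALSE]
    z12 <- z[bi$lo, bj$hi, drop = FALSE]; z22 <- z[bi$hi, bj$hi, drop = FALSE]
    out[t, , ] <- outer(wlat_lo, wlon_lo) * z11 + outer(wlat_hi, wlon_lo) * z21 +
      outer(wlat_lo, wlon_hi) * z12 + outer(wlat_hi, wlon_hi) * z22
  }
  grid_field(out, target, field$time, field$units, field$name)
}

#' Align a monthly seasonal cycle across hemispheres
#'
#' Southern-hemisphere cycles are rotated by 6 months so their seasonality
#' matches the northern solar cycle; northern cycles are returned unchanged.
#'
#' @param monthly_cycle Numeric vector of length 12 (Jan..Dec).
#' @param hemisphere `"north"` or `"south"`.
#' @return Length-12 numeric vector.
#' @export
hemisphere_align_seasons <- function(monthly_cycle,
                                     hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (length(monthly_cycle) != 12L)
    stop("hemisphere_align_seasons: need exactly 12 entries")
  if (hemisphere == "north") return(monthly_cycle)
  c(monthly_cycle[7:12], monthly_cycle[1:6])
}

#' Great-circle distance between two points, km
#'
#' Haversine formula on a sphere of radius 6371 km, center to center.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorized).
#' @return Distance(s) in km.
#' @export
great_circle_distance_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("great_circle_distance_km: |lat| > 90")
  r <- 6371
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# ---- climate zones -----------------------------------------------------------

ZONE_LEVELS <- c("Equatorial", "Arid", "Temperate", "Boreal", "Polar")

#' Categorical climate-zone raster
#'
#' Integer codes per cell: 0 = non-land, 1..5 = Equatorial, Arid, Temperate,
#' Boreal, Polar (the five major merged zone classes). Zones are held constant
#' in time, including under future scenarios; the Polar zone is excluded from
#' vegetation statistics by the aggregation functions.
#'
#' @param geometry A [grid_geometry()].
#' @param zone Integer `[lat, lon]` matrix with codes in 0..5.
#' @return Object of class `climate_zone_map`.
#' @export
climate_zone_map <- function(geometry, zone) {
  stopifnot(inherits(geometry, "grid_geometry"))
  zone <- matrix(as.integer(zone), length(geometry$lat), length(geometry$lon))
  if (any(is.na(zone)) || any(zone < 0L | zone > 5L))
    stop("climate_zone_map: codes must be integers in 0..5 (0 = non-land)")
  structure(list(geometry = geometry, zone = zone,
                 levels = ZONE_LEVELS),
            class = "climate_zone_map")
}

#' Synthetic latitude-band climate zones
#'
#' A deterministic stand-in for a merged Koppen-Geiger raster: zones assigned
#' by absolute latitude (Equatorial < 15, Arid 15-30, Temperate 30-50, Boreal
#' 50-66.5, Polar beyond). All cells are land.
#'
#' @param geometry A [grid_geometry()].
#' @return A [climate_zone_map()].
#' @export
synthetic_climate_zones <- function(geometry) {
  al <- abs(geometry$lat)
  code <- ifelse(al < 15, 1L, ifelse(al < 30, 2L, ifelse(al < 50, 3L,
           ifelse(al < 66.5, 4L, 5L))))
  climate_zone_map(geometry,
                   matrix(code, length(geometry$lat), length(geometry$lon)))
}
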