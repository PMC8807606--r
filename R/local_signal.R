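# Space-for-time decomposition: per year-pair and month, the observed
# temperature change at a cell whose LAI changed is split into a large-scale
# climate component, estimated by inverse-distance weighting of the changes at
# nearby stable-LAI reference cells, and the remaining vegetation-attributed
# component dT_lai = dT - dT_res.

#' All unordered year pairs
#'
#' @param years Vector of >= 2 distinct years.
#' @return Data frame with columns `y1 < y2`, one row per pair,
#'   n(n-1)/2 rows.
#' @export
enumerate_year_pairs <- function(years) {
  years <- sort(unique(years))
  n <- length(years)
  if (n < 2L) stop("enumerate_year_pairs: need at least 2 distinct years")
  cmb <- utils::combn(years, 2L)
  data.frame(y1 = cmb[1, ], y2 = cmb[2, ])
}

#' Inverse-distance-weighted residual temperature change
#'
#' The large-scale climate signal at a target cell, estimated from the
#' temperature changes observed at its stable-LAI references:
#' sum(dT_k / d_k) / sum(1 / d_k). Bounded by the min/max of the references;
#' equal distances reduce to the arithmetic mean.
#'
#' @param ref_dT Temperature changes at the reference cells, degC.
#' @param distances Center-to-center distances, km, all > 0.
#' @return The IDW estimate, degC.
#' @export
idw_residual <- function(ref_dT, distances) {
  if (length(ref_dT) == 0L) stop("idw_residual: no reference cells")
  if (length(ref_dT) != length(distances))
    stop("idw_residual: length mismatch")
  if (any(distances <= 0))
    stop("idw_residual: nonpositive distance (reference coincides with target?)")
  w <- 1 / distances
  sum(w * ref_dT) / sum(w)
}

#' Vegetation-attributed temperature change
#'
#' @param dT Observed between-year temperature change, degC.
#' @param dT_res Large-scale residual change (see [idw_residual()]), degC.
#' @return `dT - dT_res`, exactly.
#' @export
local_delta <- function(dT, dT_res) {
  if (any(!is.finite(dT)) || any(!is.finite(dT_res)))
    stop("local_delta: non-finite input")
  dT - dT_res
}

#' Stable-LAI reference cells around a target
#'
#' All cells other than the target whose center lies within `radius_km`
#' (great-circle) and whose LAI change magnitude is below
#' `stability_threshold`. An empty result is legal; the caller decides.
#'
#' @param dlai `[lat, lon]` matrix of LAI change for the pair-month.
#' @param geometry The grid's [grid_geometry()].
#' @param target Integer `c(i, j)` (lat row, lon column) of the target cell.
#' @param radius_km Search radius (default 50, the native-resolution value).
#' @param stability_threshold Max |dLAI| of a reference, m2/m2 (default 0.1).
#' @return Data frame with columns `i`, `j`, `distance_km`, `dlai`.
#' @export
find_reference_cells <- function(dlai, geometry, target, radius_km = 50,
                                 stability_threshold = 0.1) {
  stopifnot(inherits(geometry, "grid_geometry"))
  nlat <- length(geometry$lat); nlon <- length(geometry$lon)
  if (!all(dim(dlai) == c(nlat, nlon)))
    stop("find_reference_cells: dlai does not match geometry")
  i0 <- target[1]; j0 <- target[2]
  lat0 <- geometry$lat[i0]; lon0 <- geometry$lon[j0]
  latm <- matrix(geometry$lat, nlat, nlon)
  lonm <- matrix(geometry$lon, nlat, nlon, byrow = TRUE)
  d <- great_circle_distance_km(lat0, lon0, latm, lonm)
  keep <- d > 0 & d <= radius_km & !is.na(dlai) &
    abs(dlai) < stability_threshold
  keep[i0, j0] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             distance_km = d[keep], dlai = dlai[keep])
}

#' Between-year driver means for one pair-month
#'
#' The response-surface predictors are evaluated at the average of the two
#' years of each pair.
#'
#' @param SC,SW,E Driver [grid_field()]s sharing a time axis.
#' @param y1,y2 The pair's years; `month` its month.
#' @param month Month 1-12.
#' @return List of `[lat, lon]` matrices `SC_mean`, `SW_mean`, `E_mean`.
#' @export
pair_driver_means <- function(SC, SW, E, y1, y2, month) {
  tidx <- function(f, y) {
    t <- which(f$time$year == y & f$time$month == month)
    if (length(t) != 1L)
      stop("pair_driver_means: year ", y, " month ", month, " not present")
    t
  }
  mean2 <- function(f) (field_slice(f, tidx(f, y1)) +
                          field_slice(f, tidx(f, y2))) / 2
  list(SC_mean = mean2(SC), SW_mean = mean2(SW), E_mean = mean2(E))
}

# ---- vectorized decomposition engine ----------------------------------------

# shift so that S[i, j] = M[i + di, j + dj]; NA pad in lat, circular in lon
# when wrap
shift_matrix <- function(M, di, dj, wrap = FALSE) {
  n <- nrow(M); p <- ncol(M)
  S <- matrix(NA_real_, n, p)
  src_i <- seq_len(n) + di
  ok_i <- src_i >= 1L & src_i <= n
  if (!any(ok_i)) return(S)
  if (wrap) {
    src_j <- ((seq_len(p) + dj - 1L) %% p) + 1L
    S[ok_i, ] <- M[src_i[ok_i], src_j, drop = FALSE]
  } else {
    src_j <- seq_len(p) + dj
    ok_j <- src_j >= 1L & src_j <= p
    if (any(ok_j))
      S[ok_i, ok_j] <- M[src_i[ok_i], src_j[ok_j], drop = FALSE]
  }
  S
}

# candidate neighbour offsets and per-latitude-row distances/inclusion for a
# fixed great-circle radius on a regular grid
neighbour_offsets <- function(geometry, radius_km) {
  lat <- geometry$lat; nlat <- length(lat)
  nlon <- length(geometry$lon)
  dlat <- if (nlat > 1L) geometry$dlat else 180
  dlon <- if (nlon > 1L) geometry$dlon else 360
  km_per_deg <- 6371 * pi / 180
  wrap <- nlon > 1L && abs(nlon * dlon - 360) < 1e-6
  k_lat <- if (nlat > 1L) min(nlat - 1L, ceiling(radius_km / (dlat * km_per_deg)))
           else 0L
  min_cos <- max(1e-3, min(cos(lat * pi / 180)))
  k_lon_cap <- if (wrap) floor(nlon / 2) else nlon - 1L
  k_lon <- if (nlon > 1L)
    min(k_lon_cap, ceiling(radius_km / (dlon * km_per_deg * min_cos)))
    else 0L
  off <- expand.grid(di = -k_lat:k_lat, dj = -k_lon:k_lon)
  off <- off[!(off$di == 0L & off$dj == 0L), , drop = FALSE]
  no <- nrow(off)
  dist <- matrix(NA_real_, nlat, no)
  within <- matrix(FALSE, nlat, no)
  for (o in seq_len(no)) {
    src_i <- seq_len(nlat) + off$di[o]
    ok <- src_i >= 1L & src_i <= nlat
    if (!any(ok)) next
    d <- great_circle_distance_km(lat[ok], 0, lat[src_i[ok]],
                                  off$dj[o] * dlon)
    dist[ok, o] <- d
    within[ok, o] <- d > 0 & d <= radius_km
  }
  list(offsets = off, dist = dist, within = within, wrap = wrap)
}

#' Decompose observed temperature changes into local vegetation signals
#'
#' For every month and every unordered year pair, cells with |dLAI| above the
#' stability threshold are treated as targets; the residual climate signal at
#' each target is estimated by inverse-distance weighting of dT at stable-LAI
#' cells (|dLAI| below the threshold) within `radius_km`, and subtracted:
#' dT_lai = dT - dT_res. Targets with no reference are skipped and counted.
#'
#' @param obs Named list of co-registered [grid_field()]s: `LAI`, `T`, `SC`,
#'   `SW`, `E` (as produced by [generate_baseline_obs()]).
#' @param radius_km Reference search radius, km (default 50; scale with grid
#'   resolution).
#' @param stability_threshold LAI stability/retention threshold, m2/m2
#'   (default 0.1): references need |dLAI| < threshold, targets
#'   |dLAI| > threshold.
#' @param months Months to process (default 1:12).
#' @param pairs Optional data frame of year pairs (default all pairs of the
#'   observed years).
#' @param verbose Print per-stage counts.
#' @return A `data.table` of per-cell, per-month, per-pair records: `cell`,
#'   `i`, `j`, `lat`, `month`, `y1`, `y2`, `dT`, `dT_res`, `dT_lai`, `dLAI`,
#'   `dlnLAI`, `lai1`, `lai2`, `SC_mean`, `SW_mean`, `E_mean`, `n_refs`, with
#'   a `counts` attribute (targets found, targets without references).
#' @export
decompose_local_signal <- function(obs, radius_km = 50,
                                   stability_threshold = 0.1,
                                   months = 1:12, pairs = NULL,
                                   verbose = FALSE) {
  for (nm in c("LAI", "T", "SC", "SW", "E"))
    if (!inherits(obs[[nm]], "grid_field"))
      stop("decompose_local_signal: obs$", nm, " missing or not a grid_field")
  geom <- obs$LAI$geometry
  for (nm in c("T", "SC", "SW", "E"))
    if (!same_geometry(obs[[nm]]$geometry, geom))
      stop("decompose_local_signal: fields are not co-registered")
  time <- obs$LAI$time
  years <- sort(unique(time$year))
  if (is.null(pairs)) pairs <- enumerate_year_pairs(years)
  off <- neighbour_offsets(geom, radius_km)
  no <- nrow(off$offsets)
  nlat <- length(geom$lat); nlon <- length(geom$lon)
  latm <- matrix(geom$lat, nlat, nlon)
  cellm <- matrix(seq_len(nlat * nlon), nlat, nlon)
  tindex <- function(y, m) {
    t <- which(time$year == y & time$month == m)
    if (length(t) != 1L) NA_integer_ else t
  }

  out <- vector("list", nrow(pairs) * length(months))
  n_skipped <- 0L; n_targets <- 0L; n_dropped_time <- 0L
  ctr <- 0L
  for (m in months) {
    for (p in seq_len(nrow(pairs))) {
      y1 <- pairs$y1[p]; y2 <- pairs$y2[p]
      t1 <- tindex(y1, m); t2 <- tindex(y2, m)
      if (is.na(t1) || is.na(t2)) { n_dropped_time <- n_dropped_time + 1L; next }
      lai1 <- obs$LAI$values[t1, , ]; lai2 <- obs$LAI$values[t2, , ]
      dL <- lai2 - lai1
      dT <- obs$T$values[t2, , ] - obs$T$values[t1, , ]
      stable <- !is.na(dL) & !is.na(dT) & abs(dL) < stability_threshold
      ref_val <- ifelse(stable, dT, 0)
      st_num <- stable * 1
      num <- matrix(0, nlat, nlon); den <- matrix(0, nlat, nlon)
      nref <- matrix(0L, nlat, nlon)
      for (o in seq_len(no)) {
        w <- ifelse(off$within[, o], 1 / off$dist[, o], 0)
        if (all(w == 0)) next
        sv <- shift_matrix(ref_val, off$offsets$di[o], off$offsets$dj[o],
                           off$wrap)
        ss <- shift_matrix(st_num, off$offsets$di[o], off$offsets$dj[o],
                           off$wrap)
        sv[is.na(sv)] <- 0; ss[is.na(ss)] <- 0
        num <- num + w * sv
        den <- den + w * ss
        nref <- nref + (w > 0) * ss
      }
      target <- !is.na(dL) & !is.na(dT) & abs(dL) > stability_threshold
      n_targets <- n_targets + sum(target)
      n_skipped <- n_skipped + sum(target & den == 0)
      sel <- which(target & den > 0)
      if (length(sel) == 0L) next
      dT_res <- num[sel] / den[sel]
      scm <- (obs$SC$values[t1, , ][sel] + obs$SC$values[t2, , ][sel]) / 2
      swm <- (obs$SW$values[t1, , ][sel] + obs$SW$values[t2, , ][sel]) / 2
      em <- (obs$E$values[t1, , ][sel] + obs$E$values[t2, , ][sel]) / 2
      l1 <- lai1[sel]; l2 <- lai2[sel]
      dln <- ifelse(l1 > 0 & l2 > 0, log(l2 / l1), NA_real_)
      ctr <- ctr + 1L
      out[[ctr]] <- data.table::data.table(
        cell = cellm[sel],
        i = ((cellm[sel] - 1L) %% nlat) + 1L,
        j = ((cellm[sel] - 1L) %/% nlat) + 1L,
        lat = latm[sel], month = m, y1 = y1, y2 = y2,
        dT = dT[sel], dT_res = dT_res, dT_lai = dT[sel] - dT_res,
        dLAI = dL[sel], dlnLAI = dln, lai1 = l1, lai2 = l2,
        SC_mean = scm, SW_mean = swm, E_mean = em,
        n_refs = nref[sel])
    }
  }
  records <- if (ctr > 0) data.table::rbindlist(out[seq_len(ctr)])
             else data.table::data.table()
  attr(records, "counts") <- list(targets = n_targets,
                                  no_reference = n_skipped,
                                  missing_pair_months = n_dropped_time,
                                  records = nrow(records))
  if (verbose)
    message(sprintf("decompose: %d targets, %d without references, %d records",
                    n_targets, n_skipped, nrow(records)))
  records
}

#' Regime-split sensitivity samples from decomposition records
#'
#' Records at or above the snow threshold (between-year mean snow cover, \%)
#' form snow-regime samples with response dT_lai / dLAI (degC per m2/m2);
#' snow-free records form samples with response dT_lai / dlnLAI (degC per
#' unit ln LAI). Snow-free records with nonpositive LAI are rejected;
#' |dlnLAI| below `dlnlai_floor` is dropped to avoid ratio blow-up.
#'
#' @param records Output of [decompose_local_signal()].
#' @param snow_threshold Snow-cover split, percent (default 1).
#' @param dlnlai_floor Minimum |dlnLAI| for snow-free samples (default 0.05).
#' @return A `data.table` of samples: record columns plus `regime`,
#'   `response`, and predictors `x` (SC_mean or E_mean) and `y` (SW_mean),
#'   with a `counts` attribute of rejection tallies.
#' @export
build_sensitivity_samples <- function(records, snow_threshold = 1,
                                      dlnlai_floor = 0.05) {
  if (nrow(records) == 0L) stop("build_sensitivity_samples: no records")
  dt <- data.table::as.data.table(records)
  snow <- dt$SC_mean >= snow_threshold
  bad_lai <- !snow & !(dt$lai1 > 0 & dt$lai2 > 0)
  small_dln <- !snow & !bad_lai & abs(dt$dlnLAI) < dlnlai_floor
  keep <- (snow | (!bad_lai & !small_dln))
  dt <- dt[keep]
  snow <- snow[keep]
  dt[, `:=`(regime = ifelse(snow, "snow", "snow_free"),
            response = ifelse(snow, dT_lai / dLAI, dT_lai / dlnLAI),
            x = ifelse(snow, SC_mean, E_mean),
            y = SW_mean)]
  dt <- dt[is.finite(response)]
  attr(dt, "counts") <- list(nonpositive_lai = sum(bad_lai),
                             below_dln_floor = sum(small_dln),
                             samples = nrow(dt))
  dt
}

#' Exclude cells with unstable per-pair sensitivity
#'
#' Within each group (default: cell and month, i.e. across the pair ensemble)
#' the sample standard deviation of the response is computed; groups with
#' s.d. above the threshold are excluded, as are groups with fewer than two
#' samples (counted separately).
#'
#' @param samples Output of [build_sensitivity_samples()].
#' @param threshold Maximum response s.d. (default 0.2).
#' @param by Grouping columns (default `c("cell", "month")`).
#' @return The retained samples (`data.table`), with a `counts` attribute
#'   (groups kept / excluded by s.d. / excluded as singletons).
#' @export
stddev_filter <- function(samples, threshold = 0.2, by = c("cell", "month")) {
  dt <- data.table::as.data.table(samples)
  g <- dt[, .(n = .N, sd = stats::sd(response)), by = by]
  keep <- g[n >= 2L & sd <= threshold]
  out <- dt[keep[, ..by], on = by]
  attr(out, "counts") <- list(groups = nrow(g),
                              kept = nrow(keep),
                              excluded_sd = sum(g$n >= 2L & g$sd > threshold),
                              excluded_singleton = sum(g$n < 2L))
  out
}

#' Area-weighted LAI-transition bin matrix
#'
#' Bins every record by its LAI in the two observation years (X axis: first
#' year, Y axis: second year), with bin edges spanning the observed pooled LAI
#' range in steps of `bin_percent` percent of that range, and computes the
#' area-weighted mean vegetation signal per bin.
#'
#' @param records Output of [decompose_local_signal()].
#' @param weights An [cell_area_weights()] on the records' geometry.
#' @param bin_percent Bin width as percent of the LAI range (default 1).
#' @return Object of class `transition_bin_matrix`: `edges`, `mean`
#'   (`[n_bins, n_bins]`, NA where empty), `area`, `count`.
#' @export
lai_transition_bins <- function(records, weights, bin_percent = 1) {
  if (nrow(records) == 0L) stop("lai_transition_bins: no records")
  stopifnot(inherits(weights, "area_weights"))
  lo <- min(records$lai1, records$lai2)
  hi <- max(records$lai1, records$lai2)
  if (hi <= lo) stop("lai_transition_bins: degenerate LAI range")
  nb <- max(1L, as.integer(round(100 / bin_percent)))
  edges <- seq(lo, hi, length.out = nb + 1L)
  bin_of <- function(v) pmin(nb, pmax(1L, findInterval(v, edges,
                                                       rightmost.closed = TRUE)))
  b1 <- bin_of(records$lai1); b2 <- bin_of(records$lai2)
  a <- weights$w[cbind(records$i, records$j)]
  dt <- data.table::data.table(b1 = b1, b2 = b2, a = a, v = records$dT_lai)
  agg <- dt[, .(wmean = sum(a * v) / sum(a), area = sum(a), n = .N),
            by = .(b1, b2)]
  mk <- function(col, fill) {
    m <- matrix(fill, nb, nb)
    m[cbind(agg$b1, agg$b2)] <- agg[[col]]
    m
  }
  structure(list(edges = edges,
                 mean = mk("wmean", NA_real_),
                 area = mk("area", 0),
                 count = mk("n", 0L)),
            class = "transition_bin_matrix")
}

#' Mean annual sensitivity map on the per-m2/m2 scale
#'
#' Converts every sample to the sensitivity of a 1 m2/m2 LAI change (snow
#' regime: the response as-is; snow-free: response times the finite ln
#' conversion at the cell's monthly LAI climatology), averages over pairs
#' within each cell-month and then over months with equal weight.
#'
#' @param samples Sensitivity samples, normally after [stddev_filter()].
#' @param lai_clim `[12, lat, lon]` array of monthly LAI climatology (e.g.
#'   per-month mean of the observed LAI over years).
#' @param geometry The grid's [grid_geometry()].
#' @param conversion `"finite"` or `"infinitesimal"` (see [ln_conversion()]).
#' @return A single-time [grid_field()], degC per m2/m2; cells with no
#'   surviving samples are missing.
#' @export
mean_annual_sensitivity_map <- function(samples, lai_clim, geometry,
                                        conversion = "finite") {
  stopifnot(inherits(geometry, "grid_geometry"))
  nlat <- length(geometry$lat); nlon <- length(geometry$lon)
  stopifnot(all(dim(lai_clim) == c(12L, nlat, nlon)))
  dt <- data.table::as.data.table(samples)
  conv <- ln_conversion(lai_clim[cbind(dt$month, dt$i, dt$j)], conversion)
  dt <- data.table::data.table(
    cell = dt$cell, i = dt$i, j = dt$j, month = dt$month,
    y1 = dt$y1, y2 = dt$y2,
    per_lai = ifelse(dt$regime == "snow", dt$response, dt$response * conv))
  bym <- dt[is.finite(per_lai),
            .(v = mean(per_lai)), by = .(cell, i, j, month)]
  bycell <- bym[, .(v = mean(v)), by = .(cell, i, j)]
  m <- matrix(NA_real_, nlat, nlon)
  m[cbind(bycell$i, bycell$j)] <- bycell$v
  grid_field(m, geometry, data.frame(year = 0L, month = 1L),
             units = "degC per m2/m2", name = "mean_annual_dT_dLAI")
}

#' Zonal median and quartiles of the per-pair sensitivity ensemble
#'
#' For each year pair, the zonal mean of the per-m2/m2 sensitivity is formed
#' (equal-weight months, valid cells per latitude row); across the pair
#' ensemble the per-row median and first/third quartiles are reported.
#'
#' @inheritParams mean_annual_sensitivity_map
#' @return Data frame with `lat`, `median`, `q1`, `q3`, `n_pairs`.
#' @export
zonal_sensitivity_summary <- function(samples, lai_clim, geometry,
                                      conversion = "finite") {
  dt <- data.table::as.data.table(samples)
  conv <- ln_conversion(lai_clim[cbind(dt$month, dt$i, dt$j)], conversion)
  dt <- data.table::data.table(
    i = dt$i, y1 = dt$y1, y2 = dt$y2,
    per_lai = ifelse(dt$regime == "snow", dt$response, dt$response * conv))
  zon <- dt[is.finite(per_lai),
            .(v = mean(per_lai)), by = .(i, y1, y2)]
  out <- zon[, .(median = stats::median(v),
                 q1 = stats::quantile(v, 0.25, names = FALSE),
                 q3 = stats::quantile(v, 0.75, names = FALSE),
                 n_pairs = .N), by = i][order(i)]
  data.frame(lat = geometry$lat[out$i], median = out$median,
             q1 = out$q1, q3 = out$q3, n_pairs = out$n_pairs)
}
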