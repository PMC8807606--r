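# Projection stage: apply a fitted sensitivity model to scenario trajectories
# to obtain the vegetation-driven biophysical temperature change, factor it
# into LAI-only / climate-change / per-driver terms, add the biochemical
# (carbon-sequestration) effect, and aggregate across zones, seasons and the
# model ensemble.

# monthly baseline climatology [12, lat, lon] of one run variable
run_baseline_clim <- function(run, var) {
  f <- run$fields[[var]]
  idx <- which(f$time$year == run$baseline_year)
  if (length(idx) != 12L)
    stop("run baseline year must carry 12 months for ", var)
  f$values[idx, , , drop = FALSE]
}

# core kernel: delta-T per time step given driver arrays and baseline LAI;
# drivers and LAI are [nt, lat, lon], baselines [12, lat, lon]
delta_T_kernel <- function(model, sc, sw, e, lai, lai_base, months) {
  out <- array(NA_real_, dim(lai))
  nt <- dim(lai)[1]
  for (t in seq_len(nt)) {
    m <- months[t]
    sc_t <- sc[t, , ]; sw_t <- sw[t, , ]; e_t <- e[t, , ]
    lai_t <- lai[t, , ]; lai_b <- lai_base[m, , ]
    snow <- !is.na(sc_t) & sc_t >= model$snow_threshold
    d <- matrix(NA_real_, nrow(sc_t), ncol(sc_t))
    if (any(snow))
      d[snow] <- eval_surface(model$snow, sc_t[snow], sw_t[snow],
                              warn_range = FALSE) *
        (lai_t[snow] - lai_b[snow])
    sf <- !is.na(sc_t) & !snow & !is.na(lai_t) & !is.na(lai_b) &
      lai_t > 0 & lai_b > 0
    if (any(sf))
      d[sf] <- eval_surface(model$snow_free, e_t[sf], sw_t[sf],
                            warn_range = FALSE) *
        (log(lai_t[sf]) - log(lai_b[sf]))
    out[t, , ] <- d
  }
  out
}

#' Vegetation-driven biophysical temperature change of a scenario run
#'
#' Per cell-month the regime is chosen by the concurrent snow cover against
#' the model's threshold; the snow surface (per m2/m2) multiplies the LAI
#' change from the baseline-year climatology, the snow-free surface (per ln
#' LAI) multiplies the ln-LAI change. Cells with nonpositive LAI in the
#' snow-free branch are missing.
#'
#' @param model A [sensitivity_model()].
#' @param run A [scenario_run()].
#' @return A [grid_field()] of ΔT (degC) on the run's full time axis.
#' @export
biophysical_delta_T <- function(model, run) {
  stopifnot(inherits(model, "sensitivity_model"),
            inherits(run, "scenario_run"))
  f <- run$fields
  lai_base <- run_baseline_clim(run, "LAI")
  vals <- delta_T_kernel(model, f$SC$values, f$SW$values, f$E$values,
                         f$LAI$values, lai_base, f$LAI$time$month)
  grid_field(vals, f$LAI$geometry, f$LAI$time, "degC", "dT_biophysical")
}

#' Factorial attribution of the projected biophysical signal
#'
#' Decomposes the all-effects signal (future drivers, future LAI) into the
#' LAI-only effect (baseline-climatology drivers, future LAI), the climate
#' effect (all minus LAI, exact by construction) and per-driver terms: each
#' driver term is the all-effects signal minus a variant in which that driver
#' is held at its baseline monthly climatology. Because the surfaces are
#' quadratic and regimes can flip with snow cover, the driver terms need not
#' add up to the climate effect; the shortfall is reported as
#' `closure_residual`, never hidden.
#'
#' @param model A [sensitivity_model()].
#' @param run A [scenario_run()]; its `baseline_year` climatology plays the
#'   role of current climate conditions.
#' @return Object of class `attribution_result` with [grid_field()]s
#'   `all_effects`, `lai_effect`, `climate_effect`, `driver_terms` (`snow`,
#'   `evap`, `solar`) and `closure_residual`.
#' @export
factorial_attribution <- function(model, run) {
  stopifnot(inherits(model, "sensitivity_model"),
            inherits(run, "scenario_run"))
  f <- run$fields
  months <- f$LAI$time$month
  nt <- dim(f$LAI$values)[1]
  lai_base <- run_baseline_clim(run, "LAI")
  base <- list(SC = run_baseline_clim(run, "SC"),
               SW = run_baseline_clim(run, "SW"),
               E = run_baseline_clim(run, "E"))
  # expand a [12, lat, lon] climatology onto the run's time axis
  expand_clim <- function(clim) {
    out <- array(NA_real_, dim(f$LAI$values))
    for (t in seq_len(nt)) out[t, , ] <- clim[months[t], , ]
    out
  }
  sc_b <- expand_clim(base$SC); sw_b <- expand_clim(base$SW)
  e_b <- expand_clim(base$E)

  all_eff <- delta_T_kernel(model, f$SC$values, f$SW$values, f$E$values,
                            f$LAI$values, lai_base, months)
  lai_eff <- delta_T_kernel(model, sc_b, sw_b, e_b,
                            f$LAI$values, lai_base, months)
  climate <- all_eff - lai_eff
  hold <- function(sc, sw, e) all_eff -
    delta_T_kernel(model, sc, sw, e, f$LAI$values, lai_base, months)
  term_snow <- hold(sc_b, f$SW$values, f$E$values)
  term_solar <- hold(f$SC$values, sw_b, f$E$values)
  term_evap <- hold(f$SC$values, f$SW$values, e_b)
  residual <- climate - (term_snow + term_solar + term_evap)

  gf <- function(v, nm) grid_field(v, f$LAI$geometry, f$LAI$time, "degC", nm)
  structure(list(all_effects = gf(all_eff, "dT_all_effects"),
                 lai_effect = gf(lai_eff, "dT_lai_effect"),
                 climate_effect = gf(climate, "dT_climate_effect"),
                 driver_terms = list(snow = gf(term_snow, "dT_snow_term"),
                                     evap = gf(term_evap, "dT_evap_term"),
                                     solar = gf(term_solar, "dT_solar_term")),
                 closure_residual = gf(residual, "dT_closure_residual")),
            class = "attribution_result")
}

#' Biochemical temperature effect of a vegetation-carbon change
#'
#' Linear carbon-temperature relation: land temperature rises 2.2 degC per
#' Tt C added to the atmosphere, so carbon moved into vegetation avoids that
#' warming. Returned with the package-wide sign convention (negative =
#' cooling): `-2.2 * dB` for a carbon gain `dB > 0`.
#'
#' @param dB Vegetation-carbon change, Tt C (vectorized).
#' @return Temperature change, degC (negative = cooling).
#' @export
biochemical_delta_T <- function(dB) {
  if (any(!is.finite(dB))) stop("biochemical_delta_T: non-finite dB")
  -2.2 * dB
}

#' Per-cell linear trend of annual means
#'
#' Ordinary least-squares slope of the annual mean against calendar year,
#' cell by cell; cells with fewer than 3 valid years are missing.
#'
#' @param field A [grid_field()] on a yearly (or yearly-by-monthly) time axis.
#' @param per Unit of the slope: `"year"`, `"decade"`, or `"period"` (the
#'   full span of the series).
#' @return A single-time [grid_field()] of slopes.
#' @export
linear_trend <- function(field, per = c("year", "decade", "period")) {
  per <- match.arg(per)
  stopifnot(inherits(field, "grid_field"))
  ann <- annual_mean(field)
  yrs <- ann$time$year
  if (length(yrs) < 3L) stop("linear_trend: need >= 3 time points")
  nlat <- dim(ann$values)[2]; nlon <- dim(ann$values)[3]
  X <- matrix(ann$values, nrow = length(yrs))   # [year, cell]
  ok <- !is.na(X)
  nv <- colSums(ok)
  Y <- ifelse(ok, X, 0)
  ty <- matrix(yrs, length(yrs), ncol(X))
  tsum <- colSums(ifelse(ok, ty, 0))
  tbar <- tsum / nv
  tc <- ifelse(ok, ty - rep(tbar, each = length(yrs)), 0)
  stt <- colSums(tc^2)
  slope <- colSums(tc * Y) / stt
  slope[nv < 3L | stt == 0] <- NA_real_
  fac <- switch(per, year = 1, decade = 10,
                period = yrs[length(yrs)] - yrs[1])
  grid_field(matrix(slope * fac, nlat, nlon), field$geometry,
             data.frame(year = yrs[1], month = 1L),
             units = paste0(field$units, " per ", per),
             name = paste0(field$name, "_trend"))
}

#' Annual means of a monthly grid field
#'
#' @param field A [grid_field()].
#' @return A [grid_field()] with one time step per year (equal-weight months;
#'   a year's cell is missing only if all its months are missing).
#' @export
annual_mean <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  yrs <- sort(unique(field$time$year))
  nlat <- dim(field$values)[2]; nlon <- dim(field$values)[3]
  out <- array(NA_real_, c(length(yrs), nlat, nlon))
  for (k in seq_along(yrs)) {
    idx <- which(field$time$year == yrs[k])
    sl <- field$values[idx, , , drop = FALSE]
    s <- colSums(ifelse(is.na(sl), 0, sl), dims = 1)
    n <- colSums(!is.na(sl), dims = 1)
    out[k, , ] <- ifelse(n > 0, s / n, NA_real_)
  }
  grid_field(out, field$geometry,
             data.frame(year = yrs, month = 1L),
             units = field$units, name = field$name)
}

#' Ensemble order statistics
#'
#' Cell-wise (or element-wise) median, quartiles, min and max across an
#' ensemble of co-registered results. Quartiles use linear interpolation
#' between order statistics (R quantile type 7), so the median of an odd-size
#' ensemble is an ensemble member value.
#'
#' @param results List (length >= 2) of numeric vectors, matrices or
#'   [grid_field()]s with identical shape.
#' @return Named list `median`, `q1`, `q3`, `min`, `max` of the common shape.
#' @export
ensemble_stats <- function(results) {
  if (length(results) < 2L) stop("ensemble_stats: need >= 2 ensemble members")
  vals <- lapply(results, function(r)
    if (inherits(r, "grid_field")) r$values else r)
  d <- dim(vals[[1]])
  stk <- do.call(rbind, lapply(vals, as.vector))
  stat <- function(f) {
    v <- apply(stk, 2, f)
    if (!is.null(d)) array(v, d) else v
  }
  list(median = stat(function(v) stats::median(v, na.rm = TRUE)),
       q1 = stat(function(v) stats::quantile(v, 0.25, na.rm = TRUE,
                                             names = FALSE, type = 7)),
       q3 = stat(function(v) stats::quantile(v, 0.75, na.rm = TRUE,
                                             names = FALSE, type = 7)),
       min = stat(function(v) suppressWarnings(min(v, na.rm = TRUE))),
       max = stat(function(v) suppressWarnings(max(v, na.rm = TRUE))))
}

#' Climate-zone aggregation with southern-season alignment
#'
#' Area-weighted aggregation of a monthly field within the four vegetated
#' zones (Equatorial, Arid, Temperate, Boreal; Polar and non-land excluded):
#' a per-zone annual series and a per-zone mean seasonal cycle in which
#' southern-hemisphere cells are first shifted by 6 months so both
#' hemispheres share the northern solar calendar.
#'
#' @param field A monthly [grid_field()].
#' @param zones A [climate_zone_map()] co-registered with `field`.
#' @param weights An [cell_area_weights()].
#' @return List with `annual` (data frame zone, year, value) and `seasonal`
#'   (data frame zone, month, value); zones with no valid cells are absent.
#' @export
climate_zone_aggregate <- function(field, zones, weights) {
  stopifnot(inherits(field, "grid_field"),
            inherits(zones, "climate_zone_map"),
            inherits(weights, "area_weights"))
  if (!same_geometry(field$geometry, zones$geometry))
    stop("climate_zone_aggregate: zones not co-registered with field")
  geom <- field$geometry
  nlat <- length(geom$lat); nlon <- length(geom$lon)
  south <- matrix(geom$lat < 0, nlat, nlon)
  yrs <- sort(unique(field$time$year))
  ann <- annual_mean(field)
  annual <- list(); seasonal <- list()
  for (z in 1:4) {
    zmask <- zones$zone == z
    if (!any(zmask)) next
    zname <- zones$levels[z]
    # annual series
    vals <- vapply(seq_along(yrs), function(k) {
      sl <- ann$values[k, , ]
      ok <- zmask & !is.na(sl) & weights$w > 0
      if (!any(ok)) return(NA_real_)
      sum(weights$w[ok] * sl[ok]) / sum(weights$w[ok])
    }, 0)
    annual[[zname]] <- data.frame(zone = zname, year = yrs, value = vals)
    # mean seasonal cycle over years, per cell, then aligned and averaged
    cyc <- array(NA_real_, c(12L, nlat, nlon))
    for (m in 1:12) {
      idx <- which(field$time$month == m)
      sl <- field$values[idx, , , drop = FALSE]
      s <- colSums(ifelse(is.na(sl), 0, sl), dims = 1)
      n <- colSums(!is.na(sl), dims = 1)
      cyc[m, , ] <- ifelse(n > 0, s / n, NA_real_)
    }
    sv <- vapply(1:12, function(m) {
      north_sl <- cyc[m, , ]
      south_m <- ((m + 5L) %% 12L) + 1L   # 6-month shift for southern cells
      south_sl <- cyc[south_m, , ]
      sl <- ifelse(south, south_sl, north_sl)
      ok <- zmask & !is.na(sl) & weights$w > 0
      if (!any(ok)) return(NA_real_)
      sum(weights$w[ok] * sl[ok]) / sum(weights$w[ok])
    }, 0)
    seasonal[[zname]] <- data.frame(zone = zname, month = 1:12, value = sv)
  }
  if (length(annual) == 0L) stop("climate_zone_aggregate: no valid zone cells")
  list(annual = do.call(rbind, c(annual, list(make.row.names = FALSE))),
       seasonal = do.call(rbind, c(seasonal, list(make.row.names = FALSE))))
}

#' Relative mitigation
#'
#' Mitigation cooling expressed as a percentage of the magnitude of the
#' scenario's overall land warming.
#'
#' @param mitigation_cooling Cooling magnitude, degC (positive number).
#' @param scenario_warming Scenario land warming, degC (nonzero).
#' @return Percent.
#' @export
relative_mitigation <- function(mitigation_cooling, scenario_warming) {
  if (any(scenario_warming == 0))
    stop("relative_mitigation: zero scenario warming")
  100 * mitigation_cooling / abs(scenario_warming)
}

#' Ensemble mitigation summary per scenario
#'
#' For each run: global land biophysical cooling (area-weighted mean ΔT over
#' the last `window` years, sign-flipped to a positive cooling magnitude),
#' biochemical cooling from the vegetation-carbon gain over the run, total
#' scenario land warming, and relative mitigation
#' 100 (biophysical + biochemical) / |warming|. Per scenario the ensemble
#' median, quartiles (type 7) and min/max are reported.
#'
#' @param runs List of [scenario_run()]s.
#' @param model A [sensitivity_model()].
#' @param weights An [cell_area_weights()] on the runs' geometry.
#' @param window Number of final years averaged (default 10).
#' @return List with `per_run` and `summary` data frames.
#' @export
mitigation_summary <- function(runs, model, weights, window = 10L) {
  per <- lapply(runs, function(run) {
    dT <- annual_mean(biophysical_delta_T(model, run))
    yrs <- dT$time$year
    sel <- yrs > max(yrs) - window
    glob <- vapply(which(sel), function(k)
      area_weighted_mean(dT$values[k, , ], weights), 0)
    bio_cool <- -mean(glob)
    dB <- run$carbon$B[nrow(run$carbon)] - run$carbon$B[1]
    chem_cool <- -biochemical_delta_T(dB)
    warming <- mean(run$warming$dT[sel])
    data.frame(model = run$model, scenario = run$scenario,
               biophysical_cooling = bio_cool,
               biochemical_cooling = chem_cool,
               total_warming = warming,
               relative_mitigation =
                 relative_mitigation(bio_cool + chem_cool, warming))
  })
  per <- do.call(rbind, per)
  qs <- function(v) c(median = stats::median(v),
                      q1 = stats::quantile(v, 0.25, names = FALSE),
                      q3 = stats::quantile(v, 0.75, names = FALSE),
                      min = min(v), max = max(v))
  summ <- do.call(rbind, lapply(split(per, per$scenario), function(d) {
    data.frame(scenario = d$scenario[1],
               stat = c("median", "q1", "q3", "min", "max"),
               biophysical_cooling = qs(d$biophysical_cooling),
               biochemical_cooling = qs(d$biochemical_cooling),
               total_warming = qs(d$total_warming),
               relative_mitigation = qs(d$relative_mitigation),
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(per_run = per, summary = summ)
}
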