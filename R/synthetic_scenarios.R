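# CMIP6-like synthetic scenario ensembles: per model x scenario trajectories
# of LAI, snow cover, shortwave radiation and evaporation on a 2-degree grid,
# plus a global vegetation-carbon stock and a global land-warming series.
# Construction guarantees the qualitative behaviour the projections rely on:
# ensemble-mean LAI increases monotonically with scenario strength, snow cover
# declines, evaporation rises except in an arid latitude band, and vegetation
# carbon tracks global LAI through a single proportionality constant.

#' Default 2-degree scenario geometry (meridional strip, 59S-79N)
#'
#' A 70 x 10 cell strip at 2-degree spacing covering all climate zones. The
#' spacing matches the common regridded model resolution; the longitudinal
#' extent is reduced so a full multi-model ensemble fits in desk-scale memory.
#' @return A [grid_geometry()].
#' @export
default_scenario_geometry <- function() {
  grid_geometry(lat = seq(-59, 79, by = 2), lon = seq(-9, 9, by = 2),
                lon_convention = "pm180")
}

#' Configuration of the synthetic scenario ensemble
#'
#' @param geometry Grid (default [default_scenario_geometry()]).
#' @param n_models Ensemble size (default 6, emulating the 18-model archive at
#'   reduced size; must be >= 2).
#' @param scenarios Named numeric vector of strictly increasing scenario
#'   strengths in (0, 1\] (default SSP126 < SSP245 < SSP370 < SSP585).
#' @param years Scenario years (default 2015:2100; the first year is the
#'   baseline reference).
#' @param lai_growth Fractional LAI increase by the final year under strength
#'   1 (default 0.35).
#' @param sc_decline Fractional snow-cover decrease by the final year under
#'   strength 1 (default 0.4).
#' @param e_trend Fractional evaporation increase by the final year under
#'   strength 1; reversed at 10\% of this rate in the arid band
#'   (15-30 deg absolute latitude) (default 0.2).
#' @param sw_trend Fractional shortwave trend under strength 1 (default
#'   -0.03, a slight dimming).
#' @param warming_2100 Global land warming by 2100 under strength 1, degC
#'   (default 5).
#' @param perturbation_sd Relative s.d. of per-model trend perturbations
#'   (default 0.15; 0 makes all models identical).
#' @param carbon_per_lai Vegetation-carbon gain per unit global-mean LAI
#'   increase, Tt C (default 0.4).
#' @param b0 Initial vegetation carbon stock, Tt C (default 0.45).
#' @param seed RNG seed.
#' @return A `scenario_synthetic_config` list.
#' @export
scenario_synthetic_config <- function(geometry = default_scenario_geometry(),
                                      n_models = 6L,
                                      scenarios = c(SSP126 = 0.25,
                                                    SSP245 = 0.5,
                                                    SSP370 = 0.75,
                                                    SSP585 = 1),
                                      years = 2015:2100,
                                      lai_growth = 0.35,
                                      sc_decline = 0.4,
                                      e_trend = 0.2,
                                      sw_trend = -0.03,
                                      warming_2100 = 5,
                                      perturbation_sd = 0.15,
                                      carbon_per_lai = 0.4,
                                      b0 = 0.45,
                                      seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (n_models < 2L) stop("n_models must be >= 2")
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be named")
  if (any(diff(scenarios) <= 0))
    stop("scenario strengths must be strictly increasing")
  if (length(years) < 2L) stop("need at least 2 scenario years")
  structure(list(geometry = geometry, n_models = as.integer(n_models),
                 scenarios = scenarios, years = years,
                 lai_growth = lai_growth, sc_decline = sc_decline,
                 e_trend = e_trend, sw_trend = sw_trend,
                 warming_2100 = warming_2100,
                 perturbation_sd = perturbation_sd,
                 carbon_per_lai = carbon_per_lai, b0 = b0,
                 seed = as.integer(seed)),
            class = "scenario_synthetic_config")
}

#' One model x scenario bundle of driver/LAI/carbon trajectories
#'
#' @param model Model name.
#' @param scenario Scenario name.
#' @param fields Named list of [grid_field()]s `LAI`, `SC`, `SW`, `E` on a
#'   yearly-by-monthly time axis.
#' @param carbon Data frame `year`, `B` (global vegetation carbon, Tt C,
#'   nonnegative).
#' @param warming Data frame `year`, `dT` (global land warming relative to
#'   the baseline year, degC).
#' @param baseline_year Reference year for all deltas.
#' @return Object of class `scenario_run`.
#' @export
scenario_run <- function(model, scenario, fields, carbon, warming,
                         baseline_year) {
  for (nm in c("LAI", "SC", "SW", "E"))
    if (!inherits(fields[[nm]], "grid_field"))
      stop("scenario_run: fields$", nm, " missing")
  geom <- fields$LAI$geometry
  for (nm in c("SC", "SW", "E"))
    if (!same_geometry(fields[[nm]]$geometry, geom))
      stop("scenario_run: fields are not co-registered")
  if (any(carbon$B < 0)) stop("scenario_run: negative vegetation carbon")
  if (!baseline_year %in% fields$LAI$time$year)
    stop("scenario_run: baseline year not in the run")
  structure(list(model = model, scenario = scenario, fields = fields,
                 carbon = carbon, warming = warming,
                 baseline_year = baseline_year),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %s / %s, years %d-%d, baseline %d\n",
              x$model, x$scenario, min(x$fields$LAI$time$year),
              max(x$fields$LAI$time$year), x$baseline_year))
  invisible(x)
}

#' Generate a synthetic multi-model scenario ensemble
#'
#' @param config A [scenario_synthetic_config()].
#' @return List with `runs` (list of [scenario_run()], one per model x
#'   scenario) and `truth` (the true [sensitivity_model()] used by
#'   [ground_truth_delta_T()], the config, and per-model trend factors).
#' @param true_model Sensitivity model regarded as the world's truth for
#'   oracle tests (default the published surfaces).
#' @export
generate_scenario_ensemble <- function(config,
                                       true_model = published_surfaces()) {
  stopifnot(inherits(config, "scenario_synthetic_config"))
  geom <- config$geometry
  nlat <- length(geom$lat); nlon <- length(geom$lon)
  years <- config$years; ny <- length(years)
  tau <- (years - years[1]) / (years[length(years)] - years[1])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  jit <- list(sw = matrix(stats::runif(nlat * nlon, -30, 30), nlat, nlon),
              lai = matrix(stats::runif(nlat * nlon, 0, 0.6), nlat, nlon),
              sc = matrix(stats::runif(nlat * nlon, -5, 5), nlat, nlon),
              e = matrix(stats::runif(nlat * nlon, -0.3, 0.9), nlat, nlon))
  tpl <- baseline_templates(geom, jit)
  arid <- abs(geom$lat) >= 15 & abs(geom$lat) < 30
  arid_m <- matrix(arid, nlat, nlon)
  w <- cell_area_weights(geom)

  models <- sprintf("SYN-%02d", seq_len(config$n_models))
  # per-model multiplicative trend perturbations, one per driver
  pert <- array(1 + stats::rnorm(config$n_models * 4L, 0,
                                 config$perturbation_sd),
                c(config$n_models, 4L))
  time <- data.frame(year = rep(years, each = 12L), month = rep(1:12, ny))
  nt <- ny * 12L

  runs <- list()
  for (mi in seq_len(config$n_models)) {
    for (sc_name in names(config$scenarios)) {
      s <- config$scenarios[[sc_name]]
      lai <- array(NA_real_, c(nt, nlat, nlon))
      snc <- array(NA_real_, c(nt, nlat, nlon))
      sw <- array(NA_real_, c(nt, nlat, nlon))
      ev <- array(NA_real_, c(nt, nlat, nlon))
      g_lai <- s * config$lai_growth * pert[mi, 1]
      g_sc <- s * config$sc_decline * pert[mi, 2]
      g_e <- s * config$e_trend * pert[mi, 3]
      g_sw <- s * config$sw_trend * pert[mi, 4]
      for (yi in seq_len(ny)) {
        tt <- (yi - 1L) * 12L + 1:12
        lai[tt, , ] <- tpl$LAI * (1 + g_lai * tau[yi])
        snc[tt, , ] <- pmax(0, tpl$SC * (1 - g_sc * tau[yi]))
        e_fac <- 1 + g_e * tau[yi] * ifelse(arid_m, -0.1, 1)
        ev[tt, , ] <- pmax(0, sweep(tpl$E, c(2, 3), e_fac, `*`))
        sw[tt, , ] <- pmax(0, tpl$SW * (1 + g_sw * tau[yi]))
      }
      fields <- list(
        LAI = grid_field(lai, geom, time, "m2/m2", "lai"),
        SC = grid_field(snc, geom, time, "%", "snc"),
        SW = grid_field(sw, geom, time, "W/m2", "rsds"),
        E = grid_field(ev, geom, time, "mm/day", "evap"))
      # global-mean LAI trajectory -> vegetation carbon
      lai_glob <- vapply(seq_len(ny), function(yi) {
        mean(vapply(1:12, function(m)
          area_weighted_mean(lai[(yi - 1L) * 12L + m, , ], w), 0))
      }, 0)
      b_noise <- stats::rnorm(ny, 0, 0.002 * config$perturbation_sd / 0.15)
      b_noise[1] <- 0
      B <- pmax(0, config$b0 +
                  config$carbon_per_lai * (lai_glob - lai_glob[1]) + b_noise)
      warm <- config$warming_2100 * s * pert[mi, 2] * tau
      runs[[length(runs) + 1L]] <- scenario_run(
        model = models[mi], scenario = sc_name, fields = fields,
        carbon = data.frame(year = years, B = B),
        warming = data.frame(year = years, dT = warm),
        baseline_year = years[1])
    }
  }
  list(runs = runs,
       truth = list(model = true_model, config = config,
                    perturbations = pert, models = models))
}

#' Ground-truth biophysical temperature change of a scenario run
#'
#' Independent oracle for the projection stage: evaluates the stored true
#' surfaces at the run's own drivers and multiplies by the LAI change from
#' the baseline year (linear LAI change in the snow regime, ln LAI change in
#' the snow-free regime). Written as a plain per-time loop, separate from
#' [biophysical_delta_T()].
#'
#' @param truth The `truth` element of [generate_scenario_ensemble()] (or any
#'   list with a `model` [sensitivity_model()]).
#' @param run A [scenario_run()] on the same geometry.
#' @return A [grid_field()] of ΔT (degC) on the run's time axis.
#' @export
ground_truth_delta_T <- function(truth, run) {
  model <- truth$model
  stopifnot(inherits(model, "sensitivity_model"),
            inherits(run, "scenario_run"))
  f <- run$fields
  base_t <- which(f$LAI$time$year == run$baseline_year)
  if (length(base_t) != 12L)
    stop("ground_truth_delta_T: baseline year must have 12 months")
  nt <- dim(f$LAI$values)[1]
  out <- array(NA_real_, dim(f$LAI$values))
  co_s <- model$snow$coefficients
  co_f <- model$snow_free$coefficients
  for (t in seq_len(nt)) {
    m <- f$LAI$time$month[t]
    tb <- base_t[m]
    lai_t <- f$LAI$values[t, , ]; lai_b <- f$LAI$values[tb, , ]
    sc <- f$SC$values[t, , ]; sw <- f$SW$values[t, , ]; e <- f$E$values[t, , ]
    snow <- !is.na(sc) & sc >= model$snow_threshold
    d <- matrix(NA_real_, nrow(sc), ncol(sc))
    sur_s <- co_s[["a_xx"]] * sc * sc + co_s[["a_yy"]] * sw * sw +
      co_s[["a_xy"]] * sc * sw + co_s[["b_x"]] * sc + co_s[["b_y"]] * sw +
      co_s[["c"]]
    d[snow] <- sur_s[snow] * (lai_t[snow] - lai_b[snow])
    sf <- !is.na(sc) & !snow & !is.na(lai_t) & !is.na(lai_b) &
      lai_t > 0 & lai_b > 0
    sur_f <- co_f[["a_xx"]] * e * e + co_f[["a_yy"]] * sw * sw +
      co_f[["a_xy"]] * e * sw + co_f[["b_x"]] * e + co_f[["b_y"]] * sw +
      co_f[["c"]]
    d[sf] <- sur_f[sf] * (log(lai_t[sf]) - log(lai_b[sf]))
    out[t, , ] <- d
  }
  grid_field(out, f$LAI$geometry, f$LAI$time, "degC", "dT_lai_truth")
}
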