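# Synthetic observation-like baseline with a known injected LAI-temperature
# sensitivity. The generated world:
#   T(c,m,y) = Tclim(c,m) + C(c,m,y) + V(c,m,y) + eps
# where C is a large-scale anomaly shared among neighbouring cells, V is the
# vegetation-attributed signal implied by the true sensitivity surfaces and
# the cell's LAI anomaly, and eps is observation noise. Drivers (SC, SW, E)
# are deterministic latitude/month templates plus static per-cell jitter, so
# between-year driver means equal the templates exactly and noise-free
# decomposition recovers the injected surfaces to machine precision.

#' Default baseline geometry (60 lat x 120 lon spanning 60S-80N)
#' @return A [grid_geometry()].
#' @export
default_baseline_geometry <- function() {
  dlat <- 140 / 60
  grid_geometry(lat = -60 + dlat / 2 + (0:59) * dlat,
                lon = -180 + 1.5 + (0:119) * 3,
                lon_convention = "pm180")
}

#' Configuration of the synthetic observation baseline
#'
#' @param geometry Grid to generate on (default [default_baseline_geometry()]).
#' @param years Observation years (default 2003:2014, giving 66 year pairs).
#' @param true_model Injected [sensitivity_model()] (default the published
#'   surfaces, so recovery tests target printed coefficients).
#' @param climate_sd Inter-annual s.d. of the large-scale temperature anomaly
#'   amplitudes, degC (default 0.5).
#' @param n_climate_modes Number of spatial anomaly modes, 1..5. Mode 1 is
#'   spatially uniform (infinite correlation length); higher modes add smooth
#'   low-order lat/lon polynomials and harmonics for stress tests (default 1).
#' @param obs_noise_sd Independent temperature observation noise s.d., degC
#'   (default 0).
#' @param stable_fraction Target fraction of stable-LAI cells, in (0, 1\];
#'   stable cells are laid out on a deterministic lattice guaranteeing every
#'   changing cell a nearby reference (default 1/3).
#' @param radius_km Neighbourhood radius the generated world must satisfy; at
#'   this geometry's ~2.3 degree spacing the 50 km radius of a 0.05 degree
#'   product is rescaled to 400 km (~1.5 cells).
#' @param lai_step Spacing of per-year LAI anomaly levels, m2/m2; pairwise LAI
#'   changes of changing cells are multiples of this and always exceed the
#'   0.1 m2/m2 stability threshold (default 0.12).
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return A `baseline_synthetic_config` list.
#' @export
baseline_synthetic_config <- function(geometry = default_baseline_geometry(),
                                      years = 2003:2014,
                                      true_model = published_surfaces(),
                                      climate_sd = 0.5,
                                      n_climate_modes = 1L,
                                      obs_noise_sd = 0,
                                      stable_fraction = 1 / 3,
                                      radius_km = 400,
                                      lai_step = 0.12,
                                      seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"),
            inherits(true_model, "sensitivity_model"))
  if (length(unique(years)) < 2L) stop("need at least 2 years")
  if (stable_fraction <= 0 || stable_fraction > 1)
    stop("stable_fraction must be in (0, 1]")
  if (obs_noise_sd < 0 || climate_sd < 0) stop("noise s.d. must be >= 0")
  if (n_climate_modes < 1L || n_climate_modes > 5L)
    stop("n_climate_modes must be in 1..5")
  if (lai_step <= 0.1)
    stop("lai_step must exceed the 0.1 m2/m2 stability threshold")
  structure(list(geometry = geometry, years = sort(unique(years)),
                 true_model = true_model, climate_sd = climate_sd,
                 n_climate_modes = as.integer(n_climate_modes),
                 obs_noise_sd = obs_noise_sd,
                 stable_fraction = stable_fraction,
                 radius_km = radius_km, lai_step = lai_step,
                 seed = as.integer(seed)),
            class = "baseline_synthetic_config")
}

# seasonality index: +1 local summer, -1 local winter (southern hemisphere
# phase-shifted by 6 months)
seasonality_index <- function(lat, month) {
  s_north <- cos(2 * pi * (month - 7) / 12)
  outer(ifelse(lat >= 0, 1, -1), s_north)  # [lat, month]
}

# deterministic driver templates [12, nlat, nlon] given static cell jitter
baseline_templates <- function(geometry, jit) {
  lat <- geometry$lat; lon <- geometry$lon
  nlat <- length(lat); nlon <- length(lon)
  seas <- seasonality_index(lat, 1:12)              # [lat, month]
  decl <- 23.4 * cos(2 * pi * ((1:12) - 6) / 12)    # solar declination-like
  arr <- function() array(NA_real_, c(12L, nlat, nlon))
  LAI <- arr(); SC <- arr(); SW <- arr(); E <- arr(); TT <- arr()
  for (m in 1:12) {
    sw_lat <- 320 * cos(pmin(89, abs(lat - decl[m])) * pi / 180)
    sw <- pmax(0, matrix(sw_lat, nlat, nlon) + jit$sw)
    lai <- 1 + 3 * exp(-((abs(lat) - 10) / 35)^2) *
      (0.85 + 0.15 * seas[, m])
    lai <- matrix(lai, nlat, nlon) + jit$lai
    winter <- (1 - seas[, m]) / 2
    sc_lat <- 100 * stats::plogis((abs(lat) + 30 * winter - 75) / 8)
    sc <- pmin(100, pmax(0, matrix(sc_lat, nlat, nlon) + jit$sc))
    e <- pmin(8, pmax(0, 0.25 + 0.0045 * sw + 0.42 * lai + jit$e))
    tt <- 30 * cos(lat * pi / 180) - 5 + 10 * seas[, m]
    LAI[m, , ] <- lai; SC[m, , ] <- sc; SW[m, , ] <- sw; E[m, , ] <- e
    TT[m, , ] <- matrix(tt, nlat, nlon)
  }
  list(LAI = LAI, SC = SC, SW = SW, E = E, T = TT)
}

# smooth large-scale anomaly modes, [nlat, nlon] each
anomaly_modes <- function(geometry, n_modes) {
  lat <- geometry$lat; lon <- geometry$lon
  nlat <- length(lat); nlon <- length(lon)
  latn <- lat / 90
  modes <- list(matrix(1, nlat, nlon),
                matrix(latn, nlat, nlon),
                outer(rep(1, nlat), sin(lon * pi / 180)),
                outer(rep(1, nlat), cos(lon * pi / 180)),
                matrix(latn^2 - mean(latn^2), nlat, nlon))
  modes[seq_len(n_modes)]
}

#' Generate a synthetic observation baseline with known ground truth
#'
#' Emulates the co-registered monthly LAI / air-temperature / snow-cover /
#' shortwave / evaporation record the decomposition consumes, with the
#' vegetation signal injected from `config$true_model`. Stable-LAI cells sit
#' on a lattice so that every changing cell has at least one stable reference
#' within `config$radius_km` (asserted; violation is a generation error).
#'
#' @param config A [baseline_synthetic_config()].
#' @return List with `obs` (named [grid_field()]s `LAI`, `T`, `SC`, `SW`, `E`)
#'   and `truth` (true model, driver templates, LAI climatology and per-year
#'   anomalies, injected vegetation signal, anomaly and noise fields, stable
#'   mask, regime array, and the config).
#' @export
generate_baseline_obs <- function(config) {
  stopifnot(inherits(config, "baseline_synthetic_config"))
  geom <- config$geometry
  nlat <- length(geom$lat); nlon <- length(geom$lon)
  years <- config$years; ny <- length(years)
  nt <- ny * 12L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  jit <- list(sw = matrix(stats::runif(nlat * nlon, -30, 30), nlat, nlon),
              lai = matrix(stats::runif(nlat * nlon, 0, 0.6), nlat, nlon),
              sc = matrix(stats::runif(nlat * nlon, -5, 5), nlat, nlon),
              e = matrix(stats::runif(nlat * nlon, -0.3, 0.9), nlat, nlon))
  tpl <- baseline_templates(geom, jit)

  # stable-LAI lattice: (i + j) mod k == 0, realized fraction ~ 1/k
  k <- max(1L, as.integer(round(1 / config$stable_fraction)))
  idx <- outer(seq_len(nlat), seq_len(nlon), `+`)
  stable <- (idx %% k) == 0L

  # per-year LAI anomaly levels for changing cells: a random permutation of
  # ny equispaced levels (gap = lai_step > 0.1), centered on zero
  levels <- config$lai_step * (seq_len(ny) - (ny + 1) / 2)
  a <- array(0, c(ny, nlat, nlon))
  changing <- which(!stable)
  if (length(changing) > 0) {
    perms <- vapply(changing, function(cc) sample.int(ny), integer(ny))
    for (yi in seq_len(ny)) {
      slab <- matrix(0, nlat, nlon)
      slab[changing] <- levels[perms[yi, ]]
      a[yi, , ] <- slab
    }
  }

  # reference-coverage contract at the config radius
  if (length(changing) > 0 && !any(stable))
    stop("generate_baseline_obs: no stable cells; cannot satisfy coverage")
  if (length(changing) > 0) {
    cov <- stable_coverage(stable, geom, config$radius_km)
    if (!all(cov[changing]))
      stop("generate_baseline_obs: ", sum(!cov[changing]),
           " changing cell(s) lack a stable reference within ",
           config$radius_km, " km; adjust stable_fraction or radius_km")
  }

  # anomaly amplitudes per (month, year) and mode
  modes <- anomaly_modes(geom, config$n_climate_modes)
  amp <- array(stats::rnorm(12L * ny * length(modes), 0, config$climate_sd),
               c(12L, ny, length(modes)))

  # regime per (month, cell) from the snow template
  thr <- config$true_model$snow_threshold
  regime_snow <- tpl$SC >= thr                       # [12, nlat, nlon]

  # per-cell-month true surface values
  s_snow <- eval_surface(config$true_model$snow, tpl$SC, tpl$SW,
                         warn_range = FALSE)
  s_free <- eval_surface(config$true_model$snow_free, tpl$E, tpl$SW,
                         warn_range = FALSE)

  lai <- array(NA_real_, c(nt, nlat, nlon))
  tt <- array(NA_real_, c(nt, nlat, nlon))
  veg <- array(NA_real_, c(nt, nlat, nlon))
  anom <- array(NA_real_, c(nt, nlat, nlon))
  noise <- if (config$obs_noise_sd > 0)
    array(stats::rnorm(nt * nlat * nlon, 0, config$obs_noise_sd),
          c(nt, nlat, nlon)) else array(0, c(nt, nlat, nlon))

  for (yi in seq_len(ny)) {
    ay <- a[yi, , ]
    for (m in 1:12) {
      t <- (yi - 1L) * 12L + m
      lai_my <- tpl$LAI[m, , ] + ay
      v <- ifelse(regime_snow[m, , ],
                  s_snow[m, , ] * ay,
                  s_free[m, , ] * (log(lai_my) - log(tpl$LAI[m, , ])))
      cm <- matrix(0, nlat, nlon)
      for (kk in seq_along(modes)) cm <- cm + amp[m, yi, kk] * modes[[kk]]
      lai[t, , ] <- lai_my
      veg[t, , ] <- v
      anom[t, , ] <- cm
      tt[t, , ] <- tpl$T[m, , ] + cm + v + noise[t, , ]
    }
  }

  time <- data.frame(year = rep(years, each = 12L), month = rep(1:12, ny))
  rep_tpl <- function(x) {  # recycle the 12-month template over years
    out <- array(NA_real_, c(nt, nlat, nlon))
    for (yi in seq_len(ny)) out[(yi - 1L) * 12L + 1:12, , ] <- x
    out
  }
  obs <- list(
    LAI = grid_field(lai, geom, time, "m2/m2", "lai"),
    T   = grid_field(tt, geom, time, "degC", "tas"),
    SC  = grid_field(rep_tpl(tpl$SC), geom, time, "%", "snc"),
    SW  = grid_field(rep_tpl(tpl$SW), geom, time, "W/m2", "rsds"),
    E   = grid_field(rep_tpl(tpl$E), geom, time, "mm/day", "evap"))
  truth <- list(model = config$true_model, templates = tpl,
                lai_anom = a, veg_signal = veg, anomaly = anom,
                regime_snow = regime_snow, stable = stable,
                surface_snow = s_snow, surface_snow_free = s_free,
                config = config)
  list(obs = obs, truth = truth)
}

# TRUE per cell if a stable cell lies within radius_km (excluding itself);
# stable cells are trivially covered
stable_coverage <- function(stable, geometry, radius_km) {
  off <- neighbour_offsets(geometry, radius_km)
  cov <- matrix(FALSE, nrow(stable), ncol(stable))
  st_num <- stable * 1
  for (o in seq_len(nrow(off$offsets))) {
    wcol <- off$within[, o]
    if (!any(wcol)) next
    sh <- shift_matrix(st_num, off$offsets$di[o], off$offsets$dj[o], off$wrap)
    sh[is.na(sh)] <- 0
    cov <- cov | (sh > 0 & matrix(wcol, nrow(stable), ncol(stable)))
  }
  cov | stable
}
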