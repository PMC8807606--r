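# Shared fixtures. Unit tests run on down-scaled grids; the acceptance file
# uses the default (full-size) configs and caches the expensive products.

# 16 x 24 grid over the default domain (60S-80N); ~8.75 deg spacing, so the
# reference radius is rescaled to 1200 km (~1.4 cells), the same cell-relative
# scale as the 400 km default on the 60 x 120 grid.
tiny_geometry <- function() {
  grid_geometry(lat = -60 + 4.375 + (0:15) * 8.75,
                lon = -180 + 7.5 + (0:23) * 15)
}

tiny_baseline_config <- function(seed = 1L, radius_km = 1200, ...) {
  baseline_synthetic_config(geometry = tiny_geometry(),
                            radius_km = radius_km, seed = seed, ...)
}

tiny_scenario_config <- function(seed = 1L, ...) {
  scenario_synthetic_config(
    geometry = grid_geometry(lat = seq(-58, 78, 8), lon = seq(-8, 8, 4)),
    n_models = 3L, years = 2015:2045, seed = seed, ...)
}

# 2 x 2 degree toy geometry for hand-checkable examples
micro_geometry <- function(lat = c(0, 10), lon = c(0, 10)) {
  grid_geometry(lat = lat, lon = lon)
}

const_field <- function(value, geometry, nt = 1L, units = "degC",
                        name = "x") {
  grid_field(array(value, c(nt, length(geometry$lat), length(geometry$lon))),
             geometry,
             data.frame(year = rep(2000L, nt), month = seq_len(nt)),
             units, name)
}

# full-size products shared by the acceptance criteria (computed once)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_baseline <- function() {
  if (!is.null(.acceptance_cache$base)) return(.acceptance_cache$base)
  cfg <- baseline_synthetic_config(seed = 101L)   # default: noise-free
  sim <- generate_baseline_obs(cfg)
  rec <- decompose_local_signal(sim$obs, radius_km = cfg$radius_km)
  smp <- build_sensitivity_samples(rec)
  rm(rec)
  smp <- smp[, c("cell", "i", "j", "month", "regime", "response", "x", "y")]
  .acceptance_cache$base <- list(cfg = cfg, truth = sim$truth, samples = smp)
  .acceptance_cache$base
}
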