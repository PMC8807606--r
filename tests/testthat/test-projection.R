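test_that("biophysical delta T: null change, unit ln change, regime branches", {
  m <- published_surfaces()
  g <- micro_geometry()
  years <- 2015:2017
  time <- data.frame(year = rep(years, each = 12), month = rep(1:12, 3))
  nt <- nrow(time)
  mk <- function(v, units, name)
    grid_field(array(v, c(nt, 2, 2)), g, time, units, name)
  # LAI constant -> zero everywhere
  run <- scenario_run("m", "s",
                      list(LAI = mk(1.5, "m2/m2", "lai"),
                           SC = mk(0, "%", "snc"),
                           SW = mk(0, "W/m2", "rsds"),
                           E = mk(0, "mm/day", "evap")),
                      carbon = data.frame(year = years, B = 0.4),
                      warming = data.frame(year = years, dT = 0:2),
                      baseline_year = 2015L)
  dT <- biophysical_delta_T(m, run)
  expect_true(all(dT$values == 0))
  # LAI 1 -> e under snow-free drivers at the origin: 0.42 degC
  lai <- array(1, c(nt, 2, 2)); lai[time$year > 2015, , ] <- exp(1)
  run2 <- run; run2$fields$LAI <- grid_field(lai, g, time, "m2/m2", "lai")
  dT2 <- biophysical_delta_T(m, run2)
  expect_equal(dT2$values[nt, , ], matrix(0.42, 2, 2), tolerance = 1e-12)
  expect_true(all(dT2$values[1:12, , ] == 0))
  # snow branch: SC = 100, SW = 0, LAI +1 -> snow surface at (100, 0)
  run3 <- run2; run3$fields$SC <- mk(100, "%", "snc")
  lai3 <- array(1, c(nt, 2, 2)); lai3[time$year > 2015, , ] <- 2
  run3$fields$LAI <- grid_field(lai3, g, time, "m2/m2", "lai")
  dT3 <- biophysical_delta_T(m, run3)
  expect_equal(dT3$values[nt, 1, 1], eval_surface(m$snow, 100, 0))
})

test_that("oracle equivalence on synthetic runs is bit-for-bit", {
  ens <- generate_scenario_ensemble(tiny_scenario_config(seed = 31))
  for (run in ens$runs[c(1, 6, 12)]) {
    impl <- biophysical_delta_T(ens$truth$model, run)
    oracle <- ground_truth_delta_T(ens$truth, run)
    expect_identical(impl$values, oracle$values)
  }
})

test_that("attribution closes exactly and reports residuals honestly", {
  ens <- generate_scenario_ensemble(tiny_scenario_config(seed = 41))
  m <- published_surfaces()
  run <- ens$runs[[8]]
  att <- factorial_attribution(m, run)
  gap <- att$all_effects$values - att$lai_effect$values -
    att$climate_effect$values
  expect_identical(max(abs(gap), na.rm = TRUE), 0)
  # residual = climate - sum(driver terms), stored not hidden
  resid2 <- att$climate_effect$values -
    (att$driver_terms$snow$values + att$driver_terms$evap$values +
       att$driver_terms$solar$values)
  expect_equal(att$closure_residual$values, resid2)
  # drivers at baseline -> climate effect and every driver term are zero
  runb <- run
  for (nm in c("SC", "SW", "E")) {
    v <- runb$fields[[nm]]$values
    base <- v[1:12, , , drop = FALSE]
    for (t in seq_len(dim(v)[1])) v[t, , ] <- base[((t - 1) %% 12) + 1, , ]
    runb$fields[[nm]]$values <- v
  }
  attb <- factorial_attribution(m, runb)
  expect_equal(max(abs(attb$climate_effect$values), na.rm = TRUE), 0)
  for (term in attb$driver_terms)
    expect_equal(max(abs(term$values), na.rm = TRUE), 0)
})

test_that("linearized surfaces make driver terms additive", {
  lin <- function(s) quadratic_surface(
    replace(s$coefficients, c("a_xx", "a_yy", "a_xy"), 0),
    s$regime, s$response_scale)
  m <- published_surfaces()
  mlin <- sensitivity_model(lin(m$snow), lin(m$snow_free))
  # regime-stable world (no snow trend) so no cell flips surfaces
  ens <- generate_scenario_ensemble(tiny_scenario_config(seed = 51,
                                                         sc_decline = 0))
  att <- factorial_attribution(mlin, ens$runs[[4]])
  expect_lt(max(abs(att$closure_residual$values), na.rm = TRUE), 1e-9)
})

test_that("biochemical effect is linear with the printed slope", {
  expect_equal(abs(biochemical_delta_T(1)), 2.2)
  expect_equal(biochemical_delta_T(0), 0)
  expect_equal(abs(biochemical_delta_T(0.5)), 1.1)
  expect_lt(biochemical_delta_T(1), 0)       # carbon gain -> cooling
  # homogeneous of degree 1
  set.seed(8)
  db <- rnorm(10)
  expect_equal(biochemical_delta_T(3.7 * db), 3.7 * biochemical_delta_T(db))
  expect_error(biochemical_delta_T(NA), "non-finite")
})

test_that("linear trend: exact lines, constants, missing handling", {
  g <- micro_geometry()
  years <- 2001:2010
  time <- data.frame(year = rep(years, each = 12), month = rep(1:12, 10))
  vals <- array(NA_real_, c(nrow(time), 2, 2))
  for (t in seq_len(nrow(time))) {
    y <- time$year[t]
    vals[t, , ] <- matrix(c(0.01 * (y - 2001), 5, 3 - 0.2 * (y - 2001), NA),
                          2, 2)
  }
  f <- grid_field(vals, g, time, "degC", "x")
  tr <- linear_trend(f, per = "year")
  sl <- field_slice(tr, 1)
  expect_equal(sl[1, 1], 0.01, tolerance = 1e-12)
  expect_equal(sl[2, 1], 0, tolerance = 1e-12)
  expect_equal(sl[1, 2], -0.2, tolerance = 1e-12)
  expect_true(is.na(sl[2, 2]))
  expect_equal(field_slice(linear_trend(f, per = "decade"), 1)[1, 1], 0.1)
  # three-point closed form: slope of {0,1,2} on years {0,1,2} is 1
  g1 <- grid_geometry(lat = 0, lon = 0)
  f3 <- grid_field(array(c(0, 1, 2), c(3, 1, 1)), g1,
                   data.frame(year = 0:2, month = 1), "degC", "x")
  expect_equal(as.numeric(field_slice(linear_trend(f3, "year"), 1)), 1)
})

test_that("ensemble statistics follow the fixed quantile convention", {
  st <- ensemble_stats(list(c(1, 5), c(2, 5), c(4, 5)))
  expect_equal(st$median, c(2, 5))
  expect_equal(st$min, c(1, 5)); expect_equal(st$max, c(4, 5))
  # identical members collapse
  st2 <- ensemble_stats(list(1:3, 1:3, 1:3))
  expect_equal(st2$median, 1:3 + 0); expect_equal(st2$min, st2$max)
  # type-7 quartiles of {1,2,3,4}
  st3 <- ensemble_stats(list(1, 2, 3, 4))
  expect_equal(st3$q1, 1.75); expect_equal(st3$q3, 3.25)
  expect_error(ensemble_stats(list(1)), ">= 2")
})

test_that("zone aggregation weights areas and aligns southern seasons", {
  g <- grid_geometry(lat = c(-40, 40), lon = c(0, 10))  # temperate N + S
  zones <- synthetic_climate_zones(g)
  w <- cell_area_weights(g)
  time <- data.frame(year = rep(2001:2002, each = 12), month = rep(1:12, 2))
  vals <- array(0, c(24, 2, 2))
  for (t in 1:24) {
    m <- time$month[t]
    vals[t, 1, ] <- cos(2 * pi * (m - 1) / 12)   # southern cycle, Jan peak
    vals[t, 2, ] <- cos(2 * pi * (m - 7) / 12)   # northern cycle, Jul peak
  }
  f <- grid_field(vals, g, time, "degC", "x")
  agg <- climate_zone_aggregate(f, zones, w)
  seas <- agg$seasonal[agg$seasonal$zone == "Temperate", ]
  # after the 6-month southern shift both cycles coincide: July peak of 1
  expect_equal(seas$value[7], 1, tolerance = 1e-12)
  expect_equal(seas$value[1], -1, tolerance = 1e-12)
  # constant field -> every zone equals the constant; annual series flat
  fc <- grid_field(array(3, c(24, 2, 2)), g, time, "degC", "x")
  aggc <- climate_zone_aggregate(fc, zones, w)
  expect_true(all(aggc$annual$value == 3))
  expect_true(all(aggc$seasonal$value == 3))
  # hand-weighted two-cell zone: weights {1, 0.5} at values {3, 0}
  g2 <- grid_geometry(lat = c(0, 60), lon = 0)
  z2 <- climate_zone_map(g2, matrix(1L, 2, 1))   # both equatorial by fiat
  w2 <- cell_area_weights(g2)
  v2 <- array(NA_real_, c(12, 2, 1)); v2[, 1, 1] <- 3; v2[, 2, 1] <- 0
  f2 <- grid_field(v2, g2, data.frame(year = 2001L, month = 1:12),
                   "degC", "x")
  agg2 <- climate_zone_aggregate(f2, z2, w2)
  expect_equal(agg2$annual$value, 2)
  # polar-only field errors (no vegetated zone)
  gp <- grid_geometry(lat = c(70, 80), lon = 0)
  zp <- synthetic_climate_zones(gp)
  fp <- grid_field(array(1, c(12, 2, 1)), gp,
                   data.frame(year = 2001L, month = 1:12), "degC", "x")
  expect_error(climate_zone_aggregate(fp, zp, cell_area_weights(gp)),
               "no valid zone")
})

test_that("relative mitigation and the ensemble summary", {
  expect_equal(relative_mitigation(0.5, 5), 10)
  expect_equal(relative_mitigation(0, 2), 0)
  expect_equal(relative_mitigation(0.7, 2), 35)
  expect_equal(relative_mitigation(0.5, -5), 10)  # warming magnitude
  expect_error(relative_mitigation(0.5, 0), "zero")
  ens <- generate_scenario_ensemble(tiny_scenario_config(seed = 61))
  w <- cell_area_weights(ens$runs[[1]]$fields$LAI$geometry)
  mit <- mitigation_summary(ens$runs, ens$truth$model, w)
  expect_equal(nrow(mit$per_run), 12L)
  expect_true(all(mit$per_run$total_warming > 0))
  expect_true(all(mit$per_run$biochemical_cooling >= 0))
  med <- mit$summary[mit$summary$stat == "median", ]
  expect_setequal(med$scenario, names(ens$truth$config$scenarios))
  # median of an even-sized split still lies within min/max
  for (sc in med$scenario) {
    d <- mit$per_run[mit$per_run$scenario == sc, ]
    expect_gte(med$biophysical_cooling[med$scenario == sc],
               min(d$biophysical_cooling))
    expect_lte(med$biophysical_cooling[med$scenario == sc],
               max(d$biophysical_cooling))
  }
})

test_that("zone aggregation is consistent under partition refinement", {
  # splitting a zone into two sub-zones and recombining with area weights
  # reproduces the parent aggregate
  g <- grid_geometry(lat = seq(-10, 10, 5), lon = seq(0, 15, 5))
  w <- cell_area_weights(g)
  set.seed(12)
  vals <- array(rnorm(5 * 4), c(1, 5, 4))
  f <- grid_field(vals, g, data.frame(year = 2001L, month = 1L), "degC", "x")
  whole <- climate_zone_map(g, matrix(1L, 5, 4))
  left <- matrix(1L, 5, 4); left[, 3:4] <- 2L
  parts <- climate_zone_map(g, left)
  a_whole <- climate_zone_aggregate(f, whole, w)$annual$value
  ap <- climate_zone_aggregate(f, parts, w)$annual
  wa <- sum(w$w[, 1:2]); wb <- sum(w$w[, 3:4])
  recomb <- (ap$value[ap$zone == "Equatorial"] * wa +
               ap$value[ap$zone == "Arid"] * wb) / (wa + wb)
  expect_equal(recomb, a_whole, tolerance = 1e-12)
})
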