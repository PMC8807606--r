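test_that("year-pair enumeration", {
  expect_equal(nrow(enumerate_year_pairs(2003:2014)), 66L)
  expect_equal(nrow(enumerate_year_pairs(c(2001, 2002))), 1L)
  expect_equal(nrow(enumerate_year_pairs(2001:2004)), 6L)
  p <- enumerate_year_pairs(2001:2004)
  expect_true(all(p$y1 < p$y2))
  expect_error(enumerate_year_pairs(2001), "at least 2")
  expect_error(enumerate_year_pairs(c(2001, 2001)), "at least 2")
})

test_that("IDW residual: hand values, boundedness, degenerate inputs", {
  expect_equal(idw_residual(c(1.0, 0.0), c(10, 40)), 0.8)
  expect_equal(idw_residual(rep(2.5, 4), c(3, 9, 27, 45)), 2.5)
  expect_equal(idw_residual(0.7, 13), 0.7)
  # equal distances -> arithmetic mean
  expect_equal(idw_residual(c(1, 2, 6), c(5, 5, 5)), 3)
  expect_error(idw_residual(numeric(0), numeric(0)), "no reference")
  expect_error(idw_residual(c(1, 2), c(0, 5)), "nonpositive")
  # bounded by reference range
  set.seed(3)
  for (k in 1:20) {
    v <- rnorm(5); d <- runif(5, 1, 50)
    r <- idw_residual(v, d)
    expect_gte(r, min(v)); expect_lte(r, max(v))
  }
})

test_that("local delta is exact subtraction", {
  expect_equal(local_delta(0.5, 0.3), 0.2)
  expect_equal(local_delta(0.4, 0.4), 0)
  expect_equal(local_delta(-0.1, 0.2), -0.3)
  expect_error(local_delta(NA_real_, 1), "non-finite")
})

test_that("reference cell search honours radius and stability", {
  g <- grid_geometry(lat = seq(-0.9, 0.9, 0.45), lon = seq(-0.9, 0.9, 0.45))
  dl <- matrix(0.05, 5, 5)       # everything stable
  dl[3, 3] <- 0.5                # the target itself
  dl[3, 4] <- 0.15               # unstable neighbour ~50 km east
  dl[2, 3] <- NA                 # missing neighbour
  refs <- find_reference_cells(dl, g, target = c(3, 3), radius_km = 51)
  # 0.45 deg ~ 50 km: the 4-neighbourhood minus the unstable and missing ones
  expect_equal(nrow(refs), 2L)
  expect_true(all(abs(refs$dlai) < 0.1))
  expect_true(all(refs$distance_km > 0 & refs$distance_km <= 51))
  # tight radius -> empty list is legal
  refs0 <- find_reference_cells(dl, g, target = c(3, 3), radius_km = 10)
  expect_equal(nrow(refs0), 0L)
})

test_that("pair driver means average the two years", {
  g <- micro_geometry()
  time <- data.frame(year = rep(c(2003L, 2004L), each = 2), month = rep(1:2, 2))
  v <- array(0, c(4, 2, 2)); v[1, , ] <- 20; v[2, , ] <- 5
  v[3, , ] <- 40; v[4, , ] <- 15
  SC <- grid_field(v, g, time, "%", "snc")
  m <- pair_driver_means(SC, SC, SC, 2003, 2004, month = 1)
  expect_equal(m$SC_mean, matrix(30, 2, 2))
  m2 <- pair_driver_means(SC, SC, SC, 2003, 2004, month = 2)
  expect_equal(m2$SC_mean, matrix(10, 2, 2))
  expect_error(pair_driver_means(SC, SC, SC, 2003, 2005, month = 1),
               "not present")
})

test_that("vectorized decomposition agrees with the per-cell IDW oracle", {
  cfg <- tiny_baseline_config(seed = 13, obs_noise_sd = 0.1)
  sim <- generate_baseline_obs(cfg)
  rec <- decompose_local_signal(sim$obs, radius_km = cfg$radius_km,
                                months = 4L)
  time <- sim$obs$LAI$time
  set.seed(5)
  idx <- sample(nrow(rec), 30)
  for (r in idx) {
    row <- rec[r]
    t1 <- which(time$year == row$y1 & time$month == row$month)
    t2 <- which(time$year == row$y2 & time$month == row$month)
    dl <- sim$obs$LAI$values[t2, , ] - sim$obs$LAI$values[t1, , ]
    dT <- sim$obs$T$values[t2, , ] - sim$obs$T$values[t1, , ]
    refs <- find_reference_cells(dl, cfg$geometry, c(row$i, row$j),
                                 radius_km = cfg$radius_km)
    expect_equal(nrow(refs), row$n_refs)
    want_res <- idw_residual(dT[cbind(refs$i, refs$j)], refs$distance_km)
    expect_equal(row$dT_res, want_res, tolerance = 1e-10)
    expect_equal(row$dT, dT[row$i, row$j])
    expect_equal(row$dT_lai, local_delta(row$dT, row$dT_res))
  }
})

test_that("records satisfy the structural invariants", {
  cfg <- tiny_baseline_config(seed = 6)
  sim <- generate_baseline_obs(cfg)
  rec <- decompose_local_signal(sim$obs, radius_km = cfg$radius_km,
                                months = c(1L, 7L))
  # additivity holds by construction: dT_lai is stored as dT - dT_res
  expect_identical(rec$dT_lai, rec$dT - rec$dT_res)
  expect_equal(rec$dT_lai + rec$dT_res, rec$dT, tolerance = 1e-12)
  expect_true(all(abs(rec$dLAI) > 0.1))
  expect_true(all(rec$n_refs >= 1))
  expect_true(all(rec$y2 > rec$y1))
  # pair-count identity: per cell-month at most n(n-1)/2 records
  cnt <- rec[, .N, by = .(cell, month)]
  expect_lte(max(cnt$N), 66L)
})

test_that("regime split, retention rules and response scales", {
  rec <- data.table::data.table(
    cell = 1:5, i = 1L, j = 1:5, lat = 0, month = 1L, y1 = 2003L, y2 = 2004L,
    dT = 0, dT_res = 0,
    dT_lai = c(-0.2, -0.3, 0.1, 0.2, 0.1),
    dLAI = c(1.0, 1.0, 0.05, 0.5, 0.5),
    dlnLAI = c(0.5, 1.0, 0.02, 0.01, NA),
    lai1 = c(1, 1, 1, 1, -1), lai2 = c(2, exp(1), 1.05, 1.01, 0.5),
    SC_mean = c(50, 0, 0, 0, 0), SW_mean = 100, E_mean = 2, n_refs = 1L)
  # row 3 fails |dLAI|>0.1 upstream; simulate decompose output by dropping it
  rec <- rec[abs(dLAI) > 0.1]
  smp <- build_sensitivity_samples(rec, snow_threshold = 1,
                                   dlnlai_floor = 0.05)
  # row1: snow regime, response per m2/m2; row2: snow-free per ln unit;
  # row4 dropped by the dln floor; row5 rejected for nonpositive LAI
  expect_equal(nrow(smp), 2L)
  snow <- smp[smp$regime == "snow"]
  expect_equal(snow$response, -0.2)
  expect_equal(snow$x, 50); expect_equal(snow$y, 100)
  sf <- smp[smp$regime == "snow_free"]
  expect_equal(sf$response, -0.3)
  expect_equal(sf$x, 2)
  cnt <- attr(smp, "counts")
  expect_equal(cnt$nonpositive_lai, 1L)
  expect_equal(cnt$below_dln_floor, 1L)
})

test_that("s.d. filter keeps stable cells and drops volatile or singleton ones", {
  smp <- data.table::data.table(
    cell = c(1, 1, 2, 2, 3, 3, 3, 4),
    month = 1L,
    response = c(0.1, 0.1, 0.5, -0.5, 0.10, 0.12, 0.08, 9),
    regime = "snow")
  out <- stddev_filter(smp, threshold = 0.2)
  expect_setequal(unique(out$cell), c(1, 3))
  cnt <- attr(out, "counts")
  expect_equal(cnt$excluded_sd, 1L)         # cell 2: sd = 0.707
  expect_equal(cnt$excluded_singleton, 1L)  # cell 4
  # hand s.d. checks behind the filter decisions
  expect_equal(sd(c(0.5, -0.5)), 1 / sqrt(2))
  expect_equal(sd(c(0.10, 0.12, 0.08)), 0.02)
})

test_that("LAI transition bins: area weighting and degenerate range", {
  g <- grid_geometry(lat = c(0, 60), lon = c(0, 10))
  w <- cell_area_weights(g)
  rec <- data.table::data.table(
    cell = c(1L, 2L), i = c(1L, 2L), j = 1L, lat = c(0, 60), month = 1L,
    y1 = 2003L, y2 = 2004L, dT = 0, dT_res = 0,
    dT_lai = c(0.3, 0.0), dLAI = 0.5, dlnLAI = 0.4,
    lai1 = c(1.0, 1.001), lai2 = c(3.0, 3.001),
    SC_mean = 0, SW_mean = 0, E_mean = 0, n_refs = 1L)
  tb <- lai_transition_bins(rec, w, bin_percent = 1)
  expect_equal(dim(tb$mean), c(100L, 100L))
  # both records share the (first, last) bin; weights cos(0)=1, cos(60)=0.5
  expect_equal(sum(!is.na(tb$mean)), 1L)
  expect_equal(tb$mean[1, 100], (1 * 0.3 + 0.5 * 0) / 1.5)
  expect_equal(tb$count[1, 100], 2L)
  rec$lai1 <- 1; rec$lai2 <- 1
  expect_error(lai_transition_bins(rec, w), "degenerate")
  # single record -> its own value
  rec2 <- rec[1]; rec2$lai2 <- 2
  tb2 <- lai_transition_bins(rec2, w)
  expect_equal(tb2$mean[1, 100], 0.3)
})

test_that("mean annual sensitivity map converts and averages correctly", {
  g <- micro_geometry()
  lai_clim <- array(1, c(12, 2, 2))
  smp <- data.table::data.table(
    cell = c(1L, 1L, 2L), i = c(1L, 1L, 2L), j = 1L,
    month = c(1L, 2L, 1L), y1 = 2003L, y2 = 2004L,
    regime = c("snow", "snow", "snow_free"),
    response = c(-0.2, -0.4, -0.3), x = 0, y = 0)
  map <- mean_annual_sensitivity_map(smp, lai_clim, g)
  m <- field_slice(map, 1)
  expect_equal(m[1, 1], -0.3)                 # mean over two months
  expect_equal(m[2, 1], -0.3 * log(2))        # ln conversion at LAI = 1
  expect_true(is.na(m[1, 2]) && is.na(m[2, 2]))
  # all-zero responses give a zero map
  smp0 <- data.table::copy(smp); smp0$response <- 0
  expect_equal(max(abs(field_slice(mean_annual_sensitivity_map(
    smp0, lai_clim, g), 1)), na.rm = TRUE), 0)
})

test_that("noise-free recovery: responses equal the injected surfaces", {
  cfg <- tiny_baseline_config(seed = 17)
  sim <- generate_baseline_obs(cfg)
  rec <- decompose_local_signal(sim$obs, radius_km = cfg$radius_km,
                                months = c(2L, 8L))
  smp <- build_sensitivity_samples(rec)
  sn <- smp[smp$regime == "snow"]
  sf <- smp[smp$regime == "snow_free"]
  expect_gt(nrow(sn), 100); expect_gt(nrow(sf), 100)
  err_sn <- sn$response -
    eval_surface(sim$truth$model$snow, sn$x, sn$y, warn_range = FALSE)
  err_sf <- sf$response -
    eval_surface(sim$truth$model$snow_free, sf$x, sf$y, warn_range = FALSE)
  expect_lt(max(abs(err_sn)), 1e-6)
  expect_lt(max(abs(err_sf)), 1e-6)
})
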