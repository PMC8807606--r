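#' Bivariate quadratic sensitivity surface
#'
#' A response surface S(x, y) = a_xx x^2 + a_yy y^2 + a_xy x y + b_x x +
#' b_y y + c, tied to a regime and a response scale:
#' \itemize{
#'   \item snow regime: predictors (SC in \%, SWdown in W/m2), response in
#'     degC per m2/m2 of LAI change;
#'   \item snow-free regime: predictors (E in mm/day, SWdown in W/m2),
#'     response in degC per unit ln(LAI) change.
#' }
#'
#' @param coefficients Named numeric vector with elements `a_xx`, `a_yy`,
#'   `a_xy`, `b_x`, `b_y`, `c`.
#' @param regime `"snow"` or `"snow_free"`.
#' @param response_scale `"per_LAI"` or `"per_lnLAI"`.
#' @param predictors Character vector of two predictor names.
#' @param units Character vector of the two predictor units.
#' @return Object of class `quadratic_surface`.
#' @export
quadratic_surface <- function(coefficients,
                              regime = c("snow", "snow_free"),
                              response_scale = c("per_LAI", "per_lnLAI"),
                              predictors = NULL, units = NULL) {
  regime <- match.arg(regime)
  response_scale <- match.arg(response_scale)
  need <- c("a_xx", "a_yy", "a_xy", "b_x", "b_y", "c")
  if (!all(need %in% names(coefficients)))
    stop("quadratic_surface: coefficients must be named ",
         paste(need, collapse = ", "))
  coefficients <- as.numeric(coefficients[need])
  names(coefficients) <- need
  if (any(!is.finite(coefficients)))
    stop("quadratic_surface: non-finite coefficient")
  if (is.null(predictors))
    predictors <- if (regime == "snow") c("SC", "SWdown") else c("E", "SWdown")
  if (is.null(units))
    units <- if (regime == "snow") c("%", "W/m2") else c("mm/day", "W/m2")
  if (regime == "snow" && response_scale != "per_LAI")
    stop("quadratic_surface: snow regime is per_LAI")
  if (regime == "snow_free" && response_scale != "per_lnLAI")
    stop("quadratic_surface: snow-free regime is per_lnLAI")
  structure(list(coefficients = coefficients, regime = regime,
                 response_scale = response_scale,
                 predictors = predictors, units = units),
            class = "quadratic_surface")
}

#' @export
print.quadratic_surface <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<quadratic_surface> %s regime (%s), predictors %s [%s]\n",
              x$regime, x$response_scale,
              paste(x$predictors, collapse = ", "),
              paste(x$units, collapse = ", ")))
  cat(sprintf("  %.4g %s^2 + %.4g %s^2 + %.4g %s.%s + %.4g %s + %.4g %s + %.4g\n",
              co["a_xx"], x$predictors[1], co["a_yy"], x$predictors[2],
              co["a_xy"], x$predictors[1], x$predictors[2],
              co["b_x"], x$predictors[1], co["b_y"], x$predictors[2],
              co["c"]))
  invisible(x)
}

#' Evaluate a quadratic surface at predictor values
#'
#' Vectorized over `x` and `y`. Values outside the physical plausibility
#' envelope (SC 0-100 \%, SW 0-450 W/m2, E 0-10 mm/day) trigger a warning,
#' not an error.
#'
#' @param surface A [quadratic_surface()].
#' @param x First predictor (SC for snow, E for snow-free).
#' @param y Second predictor (SWdown).
#' @param warn_range Warn when predictors leave the physical envelope.
#' @return Response values (degC per m2/m2 or per unit ln LAI).
#' @export
eval_surface <- function(surface, x, y, warn_range = TRUE) {
  stopifnot(inherits(surface, "quadratic_surface"))
  if (warn_range) {
    x_rng <- if (surface$regime == "snow") c(0, 100) else c(0, 10)
    bad <- sum(x < x_rng[1] | x > x_rng[2], na.rm = TRUE) +
      sum(y < 0 | y > 450, na.rm = TRUE)
    if (bad > 0)
      warning("eval_surface: ", bad,
              " predictor value(s) outside the physical envelope")
  }
  co <- surface$coefficients
  co[["a_xx"]] * x * x + co[["a_yy"]] * y * y + co[["a_xy"]] * x * y +
    co[["b_x"]] * x + co[["b_y"]] * y + co[["c"]]
}

#' A two-regime sensitivity model
#'
#' @param snow_surface Snow-regime [quadratic_surface()] (per m2/m2).
#' @param snowfree_surface Snow-free [quadratic_surface()] (per ln LAI).
#' @param snow_threshold Monthly snow-cover split, percent (default 1).
#' @return Object of class `sensitivity_model`.
#' @export
sensitivity_model <- function(snow_surface, snowfree_surface,
                              snow_threshold = 1) {
  stopifnot(inherits(snow_surface, "quadratic_surface"),
            inherits(snowfree_surface, "quadratic_surface"))
  if (snow_surface$regime != "snow" || snowfree_surface$regime != "snow_free")
    stop("sensitivity_model: surfaces assigned to the wrong regimes")
  if (snow_threshold <= 0) stop("sensitivity_model: snow_threshold must be > 0")
  structure(list(snow = snow_surface, snow_free = snowfree_surface,
                 snow_threshold = snow_threshold),
            class = "sensitivity_model")
}

#' The published observation-derived sensitivity surfaces
#'
#' The two global response surfaces estimated from the 2003-2014 satellite
#' record: in the snow regime dT/dLAI as a quadratic in snow cover (SC, \%)
#' and downwelling shortwave (SWdown, W/m2); in the snow-free regime
#' dT/d(ln LAI) as a quadratic in land evaporation (E, mm/day) and SWdown.
#'
#' @return A [sensitivity_model()] with the printed coefficient sets and a 1\%
#'   snow-cover threshold.
#' @export
published_surfaces <- function() {
  snow <- quadratic_surface(
    c(a_xx = -1.66e-5, a_yy = -2.14e-7, a_xy = 1.56e-5,
      b_x = 2.9e-3, b_y = -8.23e-4, c = -0.011),
    regime = "snow", response_scale = "per_LAI")
  snow_free <- quadratic_surface(
    c(a_xx = 3.64e-3, a_yy = 1.17e-5, a_xy = -5.80e-5,
      b_x = 8.51e-2, b_y = -6.74e-3, c = 0.42),
    regime = "snow_free", response_scale = "per_lnLAI")
  sensitivity_model(snow, snow_free, snow_threshold = 1)
}

#' Fit a bivariate quadratic surface by ordinary least squares
#'
#' Solves the normal equations of the design (x^2, y^2, xy, x, y, 1), which is
#' order-independent and deterministic. Unweighted by default; optional
#' weights (e.g. cell areas) are supported.
#'
#' @param samples Data frame with columns `response`, `x`, `y` (one regime's
#'   sensitivity samples; see [build_sensitivity_samples()]).
#' @param regime Regime label attached to the fitted surface.
#' @param weights Optional nonnegative observation weights.
#' @return List with `surface` (a [quadratic_surface()]) and `diagnostics`
#'   (n, residual s.d., R2, coefficient covariance).
#' @export
fit_quadratic_surface <- function(samples, regime = c("snow", "snow_free"),
                                  weights = NULL) {
  regime <- match.arg(regime)
  stopifnot(all(c("response", "x", "y") %in% names(samples)))
  ok <- is.finite(samples$response) & is.finite(samples$x) & is.finite(samples$y)
  x <- samples$x[ok]; y <- samples$y[ok]; r <- samples$response[ok]
  n <- length(r)
  if (n < 6L) stop("fit_quadratic_surface: need at least 6 samples, have ", n)
  X <- cbind(a_xx = x * x, a_yy = y * y, a_xy = x * y, b_x = x, b_y = y, c = 1)
  if (!is.null(weights)) {
    w <- weights[ok]
    if (any(w < 0)) stop("fit_quadratic_surface: negative weights")
    XtX <- crossprod(X * sqrt(w))
    Xty <- crossprod(X, w * r)
  } else {
    XtX <- crossprod(X)
    Xty <- crossprod(X, r)
  }
  # equilibrate: SW^2-scale columns make raw XtX numerically singular
  s <- sqrt(diag(XtX))
  s[s == 0] <- 1
  XtXs <- XtX / tcrossprod(s)
  qrX <- qr(XtXs, tol = 1e-12)
  if (qrX$rank < 6L)
    stop("fit_quadratic_surface: rank-deficient design (rank ", qrX$rank,
         " of 6); predictors are collinear")
  beta <- drop(solve(XtXs, drop(Xty) / s)) / s
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- r - fitted
  dof <- n - 6L
  sigma2 <- if (dof > 0) sum(res^2) / dof else NA_real_
  sst <- sum((r - mean(r))^2)
  diag <- list(n = n,
               residual_sd = sqrt(sigma2),
               r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
               coef_cov = sigma2 * (solve(XtXs) / tcrossprod(s)))
  scale <- if (regime == "snow") "per_LAI" else "per_lnLAI"
  list(surface = quadratic_surface(beta, regime = regime,
                                   response_scale = scale),
       diagnostics = diag)
}

#' Finite-change ln conversion factor
#'
#' Converts a per-ln-LAI sensitivity to a per-1-m2/m2 sensitivity under the
#' assumption of a 1 m2/m2 LAI change: ln(LAI + 1) - ln(LAI) evaluated at the
#' local LAI. The infinitesimal alternative (1/LAI) is available via `mode`.
#'
#' @param lai LAI values (> 0).
#' @param mode `"finite"` (default) or `"infinitesimal"`.
#' @return Conversion factor(s).
#' @export
ln_conversion <- function(lai, mode = c("finite", "infinitesimal")) {
  mode <- match.arg(mode)
  out <- rep(NA_real_, length(lai))
  pos <- !is.na(lai) & lai > 0
  out[pos] <- if (mode == "finite") log(lai[pos] + 1) - log(lai[pos])
              else 1 / lai[pos]
  if (is.array(lai)) out <- array(out, dim(lai))
  out
}

#' Map sensitivity to a unit LAI change from driver fields
#'
#' Per cell-month: cells at or above the snow threshold are evaluated with the
#' snow surface (already per m2/m2); snow-free cells with the snow-free
#' surface converted to per m2/m2 via [ln_conversion()] at the cell's monthly
#' LAI. The annual map is the equal-weight mean over the field's months.
#'
#' @param model A [sensitivity_model()].
#' @param SC,SW,E,LAI Co-registered [grid_field()]s sharing a time axis.
#' @param annual Return the annual-mean map (default) or the monthly stack.
#' @param conversion `"finite"` or `"infinitesimal"` ln conversion.
#' @return A [grid_field()] in degC per m2/m2: a single annual-mean slice, or
#'   the per-time stack when `annual = FALSE`.
#' @export
sensitivity_map <- function(model, SC, SW, E, LAI, annual = TRUE,
                            conversion = "finite") {
  stopifnot(inherits(model, "sensitivity_model"))
  for (f in list(SC, SW, E, LAI)) {
    stopifnot(inherits(f, "grid_field"))
    if (!same_geometry(f$geometry, SC$geometry))
      stop("sensitivity_map: fields are not co-registered")
  }
  if (!all(dim(SC$values)[1] == c(dim(SW$values)[1], dim(E$values)[1],
                                  dim(LAI$values)[1])))
    stop("sensitivity_map: time axes differ")
  sc <- SC$values; sw <- SW$values; e <- E$values; lai <- LAI$values
  snow <- !is.na(sc) & sc >= model$snow_threshold
  s <- array(NA_real_, dim(sc))
  s[snow] <- eval_surface(model$snow, sc[snow], sw[snow], warn_range = FALSE)
  sf <- !is.na(sc) & !snow
  bad_lai <- sf & (is.na(lai) | lai <= 0)
  sf_ok <- sf & !bad_lai
  s[sf_ok] <- eval_surface(model$snow_free, e[sf_ok], sw[sf_ok],
                           warn_range = FALSE) *
    ln_conversion(lai[sf_ok], conversion)
  s[is.na(sw) | (sf & is.na(e))] <- NA_real_
  out <- grid_field(s, SC$geometry, SC$time, units = "degC per m2/m2",
                    name = "dT_dLAI")
  if (!annual) return(out)
  ann <- apply(s, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  grid_field(array(ann, c(1, dim(ann))), SC$geometry,
             data.frame(year = SC$time$year[1], month = 1L),
             units = "degC per m2/m2", name = "dT_dLAI_annual")
}

#' Area-weighted comparison of two maps
#'
#' Area-weighted Pearson correlation and RMSE over jointly valid cells, the
#' diagnostic used to compare observation-derived and model-driver sensitivity
#' maps.
#'
#' @param a,b `[lat, lon]` matrices or single-time [grid_field()]s on the same
#'   geometry.
#' @param weights An [cell_area_weights()].
#' @return List with `r` and `rmse`.
#' @export
compare_maps <- function(a, b, weights) {
  if (inherits(a, "grid_field")) a <- field_slice(a, 1L)
  if (inherits(b, "grid_field")) b <- field_slice(b, 1L)
  stopifnot(inherits(weights, "area_weights"))
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(weights$w)))
    stop("compare_maps: dimension mismatch")
  ok <- !is.na(a) & !is.na(b) & weights$w > 0
  if (sum(ok) < 2L) stop("compare_maps: fewer than 2 jointly valid cells")
  w <- weights$w[ok] / sum(weights$w[ok])
  av <- a[ok]; bv <- b[ok]
  ma <- sum(w * av); mb <- sum(w * bv)
  va <- sum(w * (av - ma)^2); vb <- sum(w * (bv - mb)^2)
  if (va == 0 || vb == 0)
    stop("compare_maps: constant field; correlation undefined")
  r <- sum(w * (av - ma) * (bv - mb)) / sqrt(va * vb)
  rmse <- sqrt(sum(w * (av - bv)^2))
  list(r = r, rmse = rmse)
}

#' Serialize a sensitivity model to JSON
#'
#' Coefficients, regimes, response scales, predictor names/units and the snow
#' threshold round-trip unchanged (doubles written at full precision).
#'
#' @param model A [sensitivity_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_model <- function(model, path) {
  stopifnot(inherits(model, "sensitivity_model"))
  ser <- function(s) list(coefficients = as.list(s$coefficients),
                          regime = s$regime,
                          response_scale = s$response_scale,
                          predictors = s$predictors, units = s$units)
  obj <- list(type = "sensitivity_model",
              snow_threshold = model$snow_threshold,
              snow = ser(model$snow), snow_free = ser(model$snow_free))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sensitivity model written by [write_sensitivity_model()]
#' @param path JSON file path.
#' @return A [sensitivity_model()].
#' @export
read_sensitivity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sensitivity_model"))
    stop("read_sensitivity_model: not a sensitivity model file")
  de <- function(s, regime) quadratic_surface(
    unlist(s$coefficients), regime = regime,
    response_scale = s$response_scale,
    predictors = s$predictors, units = s$units)
  sensitivity_model(de(obj$snow, "snow"), de(obj$snow_free, "snow_free"),
                    snow_threshold = obj$snow_threshold)
}
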