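# Thermal-inhibition kinetics via an Eadie-Hofstee-style linearization.
#
# Residual activity J after a 30-min treatment at temperature I (Celsius)
# is regressed on J/I:
#
#     J = I_MIN + slope * (J/I),     TC50 = |slope|
#
# with I_MAX = I_C - I_MIN, where I_C is the control-group (lowest
# temperature, 22 C) mean activity. When the slope's OLS p-value exceeds
# 0.05 the parameter set is gated as NS (not significant): TC50, I_MIN and
# I_MAX carry NS markers and only I_C is reported. An I_MIN whose
# intercept p-value exceeds 0.05 is additionally reported as "0" while the
# raw numeric estimate is preserved (and still used for I_MAX, which keeps
# the I_MAX = I_C - I_MIN identity exact).
#
# Sign convention: the linearization is written with a minus sign on the
# slope term, but the empirically fitted lines have positive slopes and
# TC50 is reported as that positive slope magnitude; the raw signed slope
# is kept in diagnostics.

#' Eadie-Hofstee transform of a thermal series
#'
#' Maps each (temperature I, residual activity J) measurement to the pair
#' (x = J/I, y = J), order preserved, one pair per measurement. The
#' control point is included.
#'
#' @param series a [thermal_series()].
#' @return data.frame with columns `x` (J/I) and `y` (J).
#' @export
eadie_hofstee_transform <- function(series) {
  I <- series$temperature
  J <- series$activity
  if (any(I == 0)) {
    stop(sprintf("temperature is 0 at row(s) %s: J/I undefined",
                 paste(which(I == 0), collapse = ", ")))
  }
  data.frame(x = J / I, y = J)
}

#' Estimate thermal-inhibition parameters
#'
#' OLS of J on J/I. The intercept is I_MIN, the slope magnitude is TC50,
#' and I_MAX = I_C - I_MIN. NS gating: if the slope p-value > `alpha` the
#' numeric estimates are withheld and NS markers are emitted (only I_C is
#' reported), matching the convention that an insignificant linearization
#' yields no usable inhibition parameters.
#'
#' @param series a [thermal_series()] with at least 4 points.
#' @param control_activity the control-group mean activity I_C; defaults
#'   to the mean activity at the lowest temperature in `series`.
#' @param alpha significance threshold for the slope term (default 0.05).
#' @return Class `"thermostability_result"`: list with `TC50`, `se_TC50`,
#'   `I_MIN`, `se_I_MIN`, `I_MIN_reported` (`0` when the intercept is not
#'   distinguishable from zero, otherwise the raw estimate), `I_MAX`,
#'   `I_C`, `slope_p`, `intercept_p`, `r_squared`, `ns_flag`, `n`,
#'   `is_relative`, and `diagnostics` (raw signed slope). When
#'   `ns_flag` is `TRUE` the numeric `TC50`/`I_MIN`/`I_MAX` are `NA` and
#'   `markers` records `"NS"` for each.
#' @export
estimate_thermal_params <- function(series, control_activity = NULL,
                                    alpha = 0.05) {
  eh <- eadie_hofstee_transform(series)
  if (nrow(eh) < 4) stop("at least 4 points are required after transform")
  if (is.null(control_activity)) {
    tmin <- control_temperature(series)
    control_activity <- mean(series$activity[series$temperature == tmin])
  }
  if (control_activity <= 0) stop("control activity I_C must be > 0")
  fit <- stats::lm(y ~ x, data = eh)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2) stop("under-determined regression: J/I has no spread")
  intercept <- unname(cf[1, "Estimate"])
  slope <- unname(cf[2, "Estimate"])
  intercept_p <- unname(cf[1, 4])
  slope_p <- unname(cf[2, 4])
  r2 <- .r_squared(eh$y, stats::fitted(fit))
  ns <- slope_p > alpha

  res <- list(
    TC50 = if (ns) NA_real_ else abs(slope),
    se_TC50 = if (ns) NA_real_ else unname(cf[2, "Std. Error"]),
    I_MIN = if (ns) NA_real_ else intercept,
    se_I_MIN = if (ns) NA_real_ else unname(cf[1, "Std. Error"]),
    I_MIN_reported = if (ns) NA_real_
                     else if (intercept_p > alpha) 0 else intercept,
    I_MAX = if (ns) NA_real_ else control_activity - intercept,
    I_C = control_activity,
    slope_p = slope_p, intercept_p = intercept_p,
    r_squared = r2, ns_flag = ns, n = nrow(eh),
    is_relative = isTRUE(attr(series, "is_relative")),
    markers = if (ns) list(TC50 = "NS", I_MIN = "NS", I_MAX = "NS")
              else list(),
    diagnostics = list(raw_slope = slope, raw_intercept = intercept)
  )
  class(res) <- "thermostability_result"
  res
}

#' @export
print.thermostability_result <- function(x, ...) {
  unit <- if (x$is_relative) "% of control" else "nmol/(mg protein.min)"
  cat("<thermostability_result>\n")
  if (x$ns_flag) {
    cat(sprintf(
      "  TC50 = NS, I_MIN = NS, I_MAX = NS (slope p = %.4g > 0.05)\n",
      x$slope_p))
  } else {
    cat(sprintf("  TC50  = %.4g +/- %.3g C\n", x$TC50, x$se_TC50))
    cat(sprintf("  I_MIN = %.4g (reported %s; intercept p = %.4g)\n",
                x$I_MIN, format(x$I_MIN_reported), x$intercept_p))
    cat(sprintf("  I_MAX = %.4g %s\n", x$I_MAX, unit))
  }
  cat(sprintf("  I_C   = %.4g %s (n = %d, r^2 = %.3f)\n",
              x$I_C, unit, x$n, x$r_squared))
  invisible(x)
}

#' Convert a thermostability result to an analysis result
#'
#' NS-gated parameters are encoded with the explicit `"NS"` marker rather
#' than omitted.
#' @param x a `thermostability_result`.
#' @param provenance optional provenance list.
#' @return An [analysis_result()].
#' @export
as_analysis_result <- function(x, provenance = list()) {
  stopifnot(inherits(x, "thermostability_result"))
  params <- if (x$ns_flag) {
    list(TC50 = "NS", I_MIN = "NS", I_MAX = "NS",
         I_C = list(estimate = x$I_C, se = NA))
  } else {
    list(TC50 = list(estimate = x$TC50, se = x$se_TC50),
         I_MIN = list(estimate = x$I_MIN, se = x$se_I_MIN),
         I_MAX = list(estimate = x$I_MAX, se = NA),
         I_C = list(estimate = x$I_C, se = NA))
  }
  analysis_result(
    stage = "estimate_thermal_params",
    parameters = params,
    diagnostics = list(slope_p = x$slope_p, intercept_p = x$intercept_p,
                       r_squared = x$r_squared, n = x$n,
                       raw_slope = x$diagnostics$raw_slope,
                       I_MIN_reported = x$I_MIN_reported),
    provenance = provenance)
}

#' Express a thermal series as percent of control
#'
#' Maps each residual activity J to `100 * J / control`, so the control
#' point maps to exactly 100. TC50 is invariant under this rescaling
#' (the slope of J on J/I is scale-free in J); I_MIN, I_MAX and I_C scale
#' with it.
#'
#' @param series a [thermal_series()] of absolute activities.
#' @param control_activity control activity (> 0); defaults to the mean
#'   activity at the lowest temperature.
#' @return A [thermal_series()] with `is_relative = TRUE`.
#' @export
relative_residual <- function(series, control_activity = NULL) {
  if (is.null(control_activity)) {
    tmin <- control_temperature(series)
    control_activity <- mean(series$activity[series$temperature == tmin])
  }
  if (control_activity <= 0) stop("control activity must be > 0")
  thermal_series(series$temperature,
                 100 * series$activity / control_activity,
                 is_relative = TRUE)
}
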