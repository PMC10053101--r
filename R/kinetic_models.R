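# Model evaluation and nonlinear least-squares fitting.
#
# Models:
#   Michaelis-Menten      v = Vmax * S / (Km + S)
#   four-parameter logistic (common dose-response form)
#                         Y = Bo + (To - Bo) / (1 + 10^((ED50 - x) * h))
#   exponential           Y = J0 * exp(b * x)
#   quadratic             Y = c0 + c1 * x + c2 * x^2
#
# All nonlinear fits are unweighted least squares via minpack.lm
# (Levenberg-Marquardt), tolerance 1e-10, <= 200 iterations, <= 5 jittered
# restarts. R^2 for nonlinear fits is 1 - SSres/SStot about the response
# mean.

.FIT_CONTROL <- function() minpack.lm::nls.lm.control(maxiter = 200,
                                                      ftol = 1e-10)
.MAX_RESTARTS <- 5

.r_squared <- function(observed, fitted) {
  sstot <- sum((observed - mean(observed))^2)
  ssres <- sum((observed - fitted)^2)
  if (sstot == 0) return(if (ssres == 0) 1 else NA_real_)
  1 - ssres / sstot
}

# Run nlsLM with jittered restarts; returns the nls object or stops with a
# fit-failure error carrying the last start values tried.
.nls_with_restarts <- function(formula, data, start, lower = NULL,
                               upper = NULL, label = "model") {
  last_err <- NULL
  for (k in 0:.MAX_RESTARTS) {
    st <- start
    if (k > 0) {
      jit <- lapply(start, function(v) v * exp(stats::runif(1, -0.5, 0.5)))
      st <- jit
    }
    fit <- tryCatch(
      if (is.null(lower)) {
        minpack.lm::nlsLM(formula, data = data, start = st,
                          control = .FIT_CONTROL())
      } else {
        minpack.lm::nlsLM(formula, data = data, start = st,
                          lower = lower, upper = upper,
                          control = .FIT_CONTROL())
      },
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    last_err <- fit
  }
  stop(sprintf("%s fit failed after %d restarts: %s (last start: %s)",
               label, .MAX_RESTARTS, conditionMessage(last_err),
               paste(sprintf("%s=%g", names(start), unlist(start)),
                     collapse = ", ")))
}

#' Evaluate the Michaelis-Menten model
#'
#' @param S substrate concentration(s) in uM, `>= 0`.
#' @param Km Michaelis constant in uM.
#' @param Vmax maximal specific activity in nmol/(mg protein.min).
#' @return `Vmax * S / (Km + S)`; 0 at `S = 0`, approaching `Vmax` as
#'   `S -> Inf`.
#' @export
eval_michaelis_menten <- function(S, Km, Vmax) {
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  Vmax * S / (Km + S)
}

#' Fit the Michaelis-Menten model by nonlinear least squares
#'
#' Unweighted Levenberg-Marquardt fit of `v = Vmax*S/(Km+S)`.
#' Starting values: `Vmax0 = max(v)`; `Km0` = the lowest substrate level
#' whose mean velocity exceeds `Vmax0/2` (median substrate level as
#' fallback).
#'
#' @param data a [kinetic_dataset()] (or data.frame with `substrate_conc`
#'   in uM and `activity`), with at least 4 distinct substrate levels.
#' @param use_replicate_means fit per-level replicate means instead of all
#'   replicate observations. Both entry modes are supported because
#'   published designs mix them; the choice is recorded in the result.
#' @return An object of class `"mm_fit"`: list with `Km`, `Vmax`, `se_Km`,
#'   `se_Vmax`, `r_squared`, `converged`, `n`, `df`,
#'   `use_replicate_means`, `fitted`, `data`.
#' @export
fit_michaelis_menten <- function(data, use_replicate_means = FALSE) {
  S <- data$substrate_conc
  v <- data$activity
  if (use_replicate_means) {
    ms <- tapply(v, S, mean)
    S <- as.numeric(names(ms))
    v <- as.numeric(ms)
  }
  if (length(unique(S)) < 4) {
    stop("at least 4 distinct substrate levels are required")
  }
  if (all(v <= 0)) {
    stop("degenerate data: all velocities are <= 0")
  }
  vmax0 <- max(v)
  mean_by_S <- tapply(v, S, mean)
  Ss <- as.numeric(names(mean_by_S))
  above <- which(as.numeric(mean_by_S) > vmax0 / 2)
  km0 <- if (length(above) > 0) max(Ss[min(above)], min(Ss[Ss > 0]))
         else stats::median(Ss[Ss > 0])
  df_fit <- data.frame(S = S, v = v)
  fit <- .nls_with_restarts(v ~ Vmax * S / (Km + S), data = df_fit,
                            start = list(Km = km0, Vmax = vmax0),
                            lower = c(Km = 1e-12, Vmax = 1e-12),
                            upper = c(Km = Inf, Vmax = Inf),
                            label = "Michaelis-Menten")
  cf <- summary(fit)$coefficients
  fitted_v <- stats::fitted(fit)
  structure(list(
    Km = unname(cf["Km", "Estimate"]),
    Vmax = unname(cf["Vmax", "Estimate"]),
    se_Km = unname(cf["Km", "Std. Error"]),
    se_Vmax = unname(cf["Vmax", "Std. Error"]),
    r_squared = .r_squared(v, fitted_v),
    converged = fit$convInfo$isConv %||% TRUE,
    n = length(v),
    df = length(v) - 2L,
    use_replicate_means = use_replicate_means,
    fitted = as.numeric(fitted_v),
    data = df_fit
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> Km = %.4g +/- %.3g uM, Vmax = %.4g +/- %.3g, R^2 = %.4f (n = %d)\n",
    x$Km, x$se_Km, x$Vmax, x$se_Vmax, x$r_squared, x$n))
  invisible(x)
}

#' Evaluate the four-parameter logistic dose-response model
#'
#' `Y = Bo + (To - Bo) / (1 + 10^((ED50 - x) * hill))`. `Bo`/`To` are the
#' plateau responses, `ED50` the half-effect dose and `hill` the steepness
#' (sign sets the direction). The base-10 exponent is clipped to +/-300 to
#' avoid overflow at extreme starting values.
#'
#' @param x dose(s), U/mg protein.
#' @param Bo,To,ED50,hill model parameters.
#' @export
eval_sigmoid <- function(x, Bo, To, ED50, hill) {
  z <- pmin(pmax((ED50 - x) * hill, -300), 300)
  Bo + (To - Bo) / (1 + 10^z)
}

#' Fit the four-parameter logistic dose-response model
#'
#' Starting values: `Bo0 = min(Y)`, `To0 = max(Y)`, `ED500` = the dose with
#' response nearest the mid-span, and `hill0 = +/- 2 / range(x)` with the
#' sign taken from the response direction (a slope-scale start; a unit
#' start overflows `10^` on wide dose axes).
#'
#' @param data data.frame with columns `dose_U_per_mg` and `activity`,
#'   at least 5 distinct doses.
#' @return An object of class `"sigmoid_fit"` with `Bo`, `To`, `ED50`,
#'   `hill`, their SEs, `r_squared`, `converged`, `n`, `df`,
#'   `ed50_in_range`.
#' @export
fit_sigmoid_dose_response <- function(data) {
  x <- data$dose_U_per_mg
  y <- data$activity
  if (length(unique(x)) < 5) {
    stop("under-determined: at least 5 distinct doses are required")
  }
  span <- max(y) - min(y)
  if (span <= 1e-12 * max(1, abs(mean(y)))) {
    stop("degenerate data: response span indistinguishable from 0")
  }
  bo0 <- min(y)
  to0 <- max(y)
  mid <- (bo0 + to0) / 2
  ed0 <- x[which.min(abs(y - mid))]
  direction <- sign(stats::cor(x, y))
  if (!is.finite(direction) || direction == 0) direction <- 1
  hill0 <- direction * 2 / max(diff(range(x)), 1)
  df_fit <- data.frame(x = x, y = y)
  # Steepness and half-effect dose are weakly identified when few doses
  # fall in the transition region, so a single start can hit a singular
  # gradient; walk a small grid of (ED50, steepness) starts and keep the
  # first converged fit. ED50 candidates: the mid-response dose, interior
  # doses, and the dose-range midpoint.
  ed_candidates <- unique(c(ed0, sort(unique(x))[-c(1, length(unique(x)))],
                            mean(range(x))))
  fit <- NULL
  last_err <- NULL
  for (mult in c(16, 4, 1, 64)) {
    for (ed in ed_candidates) {
      fit <- tryCatch(
        .nls_with_restarts(
          y ~ Bo + (To - Bo) /
            (1 + 10^(pmin(pmax((ED50 - x) * hill, -300), 300))),
          data = df_fit,
          start = list(Bo = bo0, To = to0, ED50 = ed, hill = hill0 * mult),
          label = "sigmoid dose-response"),
        error = function(e) e)
      if (!inherits(fit, "error")) break
      last_err <- fit
      fit <- NULL
    }
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop(last_err)
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  fitted_y <- stats::fitted(fit)
  ed50 <- unname(est["ED50"])
  in_range <- ed50 >= min(x) && ed50 <= max(x)
  if (!in_range) {
    warning("fitted ED50 lies outside the observed dose range")
  }
  structure(list(
    Bo = unname(est["Bo"]), To = unname(est["To"]),
    ED50 = ed50, hill = unname(est["hill"]),
    se_Bo = unname(cf["Bo", "Std. Error"]),
    se_To = unname(cf["To", "Std. Error"]),
    se_ED50 = unname(cf["ED50", "Std. Error"]),
    se_hill = unname(cf["hill", "Std. Error"]),
    r_squared = .r_squared(y, fitted_y),
    converged = fit$convInfo$isConv %||% TRUE,
    n = length(y), df = length(y) - 4L,
    ed50_in_range = in_range,
    fitted = as.numeric(fitted_y)
  ), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> Bo = %.4g, To = %.4g, ED50 = %.5g, hill = %.4g, R^2 = %.4f\n",
    x$Bo, x$To, x$ED50, x$hill, x$r_squared))
  invisible(x)
}

#' Fit an exponential thermal-response model
#'
#' `Y = J0 * exp(b * x)`. The sign of `b` is unconstrained: residual
#' activity can decay (`b < 0`) or rise (`b > 0`) with temperature.
#' Initialization is a log-space regression when all responses are
#' positive, with a direct NLS fallback otherwise. A constant series
#' returns `J0 = mean(Y)`, `b = 0` exactly.
#'
#' @param data a [thermal_series()] (or data.frame with `temperature` and
#'   `activity`), at least 3 points.
#' @return Class `"exp_fit"`: `J0`, `b`, `se_J0`, `se_b`, `r_squared`,
#'   `n`, `df`.
#' @export
fit_exponential <- function(data) {
  x <- data$temperature
  y <- data$activity
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(y) == 0) {
    return(structure(list(J0 = mean(y), b = 0, se_J0 = 0, se_b = 0,
                          r_squared = 1, n = length(y),
                          df = length(y) - 2L, fitted = y),
                     class = "exp_fit"))
  }
  if (all(y > 0)) {
    lf <- stats::lm(log(y) ~ x)
    start <- list(J0 = exp(unname(stats::coef(lf)[1])),
                  b = unname(stats::coef(lf)[2]))
  } else {
    start <- list(J0 = y[which.min(x)], b = 0.01)
  }
  df_fit <- data.frame(x = x, y = y)
  fit <- .nls_with_restarts(y ~ J0 * exp(b * x), data = df_fit,
                            start = start, label = "exponential")
  cf <- summary(fit)$coefficients
  fitted_y <- stats::fitted(fit)
  structure(list(
    J0 = unname(cf["J0", "Estimate"]), b = unname(cf["b", "Estimate"]),
    se_J0 = unname(cf["J0", "Std. Error"]),
    se_b = unname(cf["b", "Std. Error"]),
    r_squared = .r_squared(y, fitted_y),
    n = length(y), df = length(y) - 2L,
    fitted = as.numeric(fitted_y)
  ), class = "exp_fit")
}

#' Fit a quadratic thermal-response model by OLS
#'
#' `Y = c0 + c1*x + c2*x^2` via `lm()` on `[1, x, x^2]`.
#'
#' @param data a [thermal_series()] (or data.frame with `temperature` and
#'   `activity`), at least 4 points.
#' @return Class `"quad_fit"`: coefficients `c0`, `c1`, `c2` with SEs and
#'   p-values, `r_squared`, `n`, `df`.
#' @export
fit_quadratic <- function(data) {
  x <- data$temperature
  y <- data$activity
  if (length(x) < 4) stop("under-determined: at least 4 points are required")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- summary(fit)$coefficients
  structure(list(
    c0 = unname(cf[1, "Estimate"]), c1 = unname(cf[2, "Estimate"]),
    c2 = unname(cf[3, "Estimate"]),
    se_c0 = unname(cf[1, "Std. Error"]),
    se_c1 = unname(cf[2, "Std. Error"]),
    se_c2 = unname(cf[3, "Std. Error"]),
    p_c0 = unname(cf[1, 4]), p_c1 = unname(cf[2, 4]),
    p_c2 = unname(cf[3, 4]),
    r_squared = .r_squared(y, stats::fitted(fit)),
    n = length(y), df = fit$df.residual,
    fitted = as.numeric(stats::fitted(fit))
  ), class = "quad_fit")
}

#' Specific activity from a time-course slope
#'
#' OLS slope of product formed (nmol per mg protein) against time
#' (minutes): the specific activity in nmol/(mg protein.min).
#'
#' @param times time points in minutes; at least 3 including `t = 0`.
#' @param product nmol product per mg protein at each time.
#' @return list with `slope`, `se`, `r_squared`, `intercept`.
#' @export
timecourse_slope <- function(times, product) {
  if (length(times) != length(product)) {
    stop("times and product must have the same length")
  }
  if (length(times) < 3) stop("at least 3 time points are required")
  if (!any(times == 0)) stop("the time course must include t = 0")
  if (length(unique(times)) < 2) {
    stop("singular design: all time points identical")
  }
  fit <- stats::lm(product ~ times)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["times", "Estimate"]),
       se = unname(cf["times", "Std. Error"]),
       intercept = unname(cf[1, "Estimate"]),
       r_squared = .r_squared(product, stats::fitted(fit)))
}

#' Specific activity from an endpoint absorbance change
#'
#' Converts a measured absorbance change into nmol p-nitrophenol via a
#' linear calibration (`nmol = (dA - intercept) / slope`) and divides by
#' protein mass and incubation time. One activity unit (U) is 1 nmol/min,
#' expressed per mg protein.
#'
#' @param delta_absorbance absorbance change (AU).
#' @param calibration list with `slope` (AU per nmol, > 0) and optional
#'   `intercept` (AU, default 0).
#' @param protein_mg protein mass in mg (> 0).
#' @param minutes incubation time in minutes (> 0).
#' @return Specific activity in nmol/(mg protein.min).
#' @export
specific_activity <- function(delta_absorbance, calibration, protein_mg,
                              minutes) {
  slope <- calibration$slope
  intercept <- calibration$intercept %||% 0
  if (is.null(slope) || slope <= 0) stop("calibration slope must be > 0")
  if (protein_mg <= 0) stop("protein mass must be > 0")
  if (minutes <= 0) stop("incubation time must be > 0")
  nmol <- (delta_absorbance - intercept) / slope
  nmol / (protein_mg * minutes)
}
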