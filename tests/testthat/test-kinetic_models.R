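test_that("Michaelis-Menten evaluation has the textbook anchor points", {
  expect_equal(eval_michaelis_menten(100, Km = 100, Vmax = 2), 1.0)
  expect_equal(eval_michaelis_menten(0, Km = 100, Vmax = 2), 0)
  # half-saturation at the partitioned recombinant isoform's own Km
  expect_equal(eval_michaelis_menten(2102, Km = 2102.0, Vmax = 0.75), 0.375)
  expect_error(eval_michaelis_menten(-1, 100, 2), ">= 0")
})

test_that("noise-free Michaelis-Menten data is recovered to high precision", {
  d <- kinetic_dataset(c(0.25, 0.5, 1, 2, 4),
                       eval_michaelis_menten(c(0.25, 0.5, 1, 2, 4), 1, 1))
  f <- fit_michaelis_menten(d)
  expect_lt(abs(f$Km - 1), 1e-6)
  expect_lt(abs(f$Vmax - 1), 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  # the 16-level 0-6 mM design at the intrinsic-lysate kinetics
  d2 <- gen_kinetic(preset("table4-intrinsic", noise_sd = 0))
  f2 <- fit_michaelis_menten(d2)
  expect_lt(abs(f2$Km / 4068.0 - 1), 1e-6)
  expect_lt(abs(f2$Vmax / 0.89 - 1), 1e-6)
})

test_that("Michaelis-Menten property: exact recovery for random parameters", {
  set.seed(11)
  for (i in 1:20) {
    Km <- 10^stats::runif(1, 1, 3.5)   # inside the 16-level grid span
    Vmax <- 10^stats::runif(1, -1, 2)
    d <- gen_kinetic(sim_spec("michaelis_menten",
                              list(Km = Km, Vmax = Vmax),
                              noise_sd = 0, replicates = 2, seed = i))
    f <- fit_michaelis_menten(d)
    expect_lt(abs(f$Km / Km - 1), 1e-6)
    expect_lt(abs(f$Vmax / Vmax - 1), 1e-6)
  }
})

test_that("degenerate or under-determined kinetic data is refused", {
  expect_error(
    fit_michaelis_menten(kinetic_dataset(c(1, 2, 4, 8), c(0, 0, 0, 0))),
    "degenerate")
  expect_error(
    fit_michaelis_menten(kinetic_dataset(c(1, 1, 2, 2), c(1, 1, 2, 2))),
    "4 distinct")
})

test_that("replicate-mean and all-replicate entry modes both fit", {
  d <- gen_kinetic(preset("table4-total", seed = 3))
  f_all <- fit_michaelis_menten(d)
  f_mean <- fit_michaelis_menten(d, use_replicate_means = TRUE)
  expect_equal(f_all$n, 64)
  expect_equal(f_mean$n, 16)
  expect_true(f_mean$use_replicate_means)
  # same generating process: point estimates agree loosely
  expect_lt(abs(f_all$Km / f_mean$Km - 1), 0.2)
})

test_that("noise-free dose-response refits recover generating parameters", {
  d <- gen_dose_response(preset("fig5", noise_sd = 0))
  f <- fit_sigmoid_dose_response(d)
  expect_lt(abs(f$Bo / 1.98 - 1), 1e-4)
  expect_lt(abs(f$To / 4.95 - 1), 1e-4)
  expect_lt(abs(f$ED50 / 4605 - 1), 1e-4)
  expect_lt(abs(f$hill / -0.002 - 1), 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
})

test_that("degenerate dose-response inputs are refused", {
  d <- data.frame(dose_U_per_mg = c(0, 10, 100, 1000, 10000),
                  activity = rep(3.0, 5))
  expect_error(fit_sigmoid_dose_response(d), "degenerate")
  expect_error(
    fit_sigmoid_dose_response(data.frame(dose_U_per_mg = c(1, 2, 3, 4),
                                         activity = c(1, 2, 3, 4))),
    "5 distinct")
})

test_that("fitted ED50 agrees with a dense-grid half-crossing search", {
  d <- gen_dose_response(preset("fig5", seed = 21))
  f <- suppressWarnings(fit_sigmoid_dose_response(d))
  # oracle: scan the fitted curve on a fine dose grid for the point where
  # the response crosses halfway between the fitted plateaus
  grid <- seq(min(d$dose_U_per_mg), max(d$dose_U_per_mg), length.out = 20001)
  step <- diff(grid[1:2])
  yy <- eval_sigmoid(grid, f$Bo, f$To, f$ED50, f$hill)
  half <- (f$Bo + f$To) / 2
  crossing <- grid[which.min(abs(yy - half))]
  expect_lt(abs(crossing - f$ED50), step + 1e-9)
})

test_that("exponential fits recover exact and constant series", {
  d <- thermal_series(c(0, 10, 20), 2 * exp(0.1 * c(0, 10, 20)))
  f <- suppressWarnings(fit_exponential(d))
  expect_equal(f$J0, 2, tolerance = 1e-7)
  expect_equal(f$b, 0.1, tolerance = 1e-7)

  const <- thermal_series(c(22, 40, 60, 80), rep(1.5, 4))
  fc <- fit_exponential(const)
  expect_identical(fc$b, 0)
  expect_identical(fc$J0, 1.5)

  d9 <- gen_thermal(preset("fig9-exp", noise_sd = 0))
  f9 <- suppressWarnings(fit_exponential(d9))
  expect_lt(abs(f9$J0 / 3.014 - 1), 1e-6)
  expect_lt(abs(f9$b / -0.0218 - 1), 1e-6)
})

test_that("quadratic fits match the normal-equations oracle exactly", {
  x <- c(22, 40, 50, 60, 70, 80)
  y <- 1 - 0.05 * x + 0.001 * x^2
  f <- suppressWarnings(fit_quadratic(thermal_series(x, y)))
  expect_equal(c(f$c0, f$c1, f$c2), c(1, -0.05, 0.001), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  set.seed(5)
  yn <- y + stats::rnorm(length(y), 0, 0.2)
  fn <- fit_quadratic(thermal_series(x, yn))
  orc <- ols_oracle(cbind(1, x, x^2), yn)
  expect_equal(c(fn$c0, fn$c1, fn$c2), orc$beta, tolerance = 1e-12)
  expect_equal(c(fn$se_c0, fn$se_c1, fn$se_c2), unname(orc$se),
               tolerance = 1e-12)

  d8 <- gen_thermal(preset("fig8-quad", noise_sd = 0))
  f8 <- suppressWarnings(fit_quadratic(d8))
  expect_equal(c(f8$c0, f8$c1, f8$c2), c(2.209, -0.064, 0.0007),
               tolerance = 1e-9)
  expect_error(fit_quadratic(thermal_series(c(1, 2, 3), c(1, 2, 3))),
               "under-determined")
})

test_that("time-course slopes equal the closed-form OLS oracle", {
  expect_equal(
    suppressWarnings(timecourse_slope(c(0, 15, 30, 45),
                                      c(0, 15, 30, 45)))$slope, 1.0)
  expect_equal(
    suppressWarnings(timecourse_slope(c(0, 15, 30, 45), rep(2, 4)))$slope,
    0)

  set.seed(9)
  t <- c(0, 15, 30, 45)
  p <- 0.8 * t + stats::rnorm(4, 0, 0.5)
  r <- timecourse_slope(t, p)
  orc <- ols_oracle(cbind(1, t), p)
  expect_equal(r$slope, orc$beta[2], tolerance = 1e-12)
  expect_equal(r$se, unname(orc$se[2]), tolerance = 1e-12)

  expect_error(timecourse_slope(c(15, 30, 45), c(1, 2, 3)), "t = 0")
  expect_error(timecourse_slope(c(0, 0, 0), c(1, 2, 3)), "singular")
})

test_that("specific activity conversion follows the unit definition", {
  cal <- list(slope = 0.01)   # AU per nmol
  # 30 nmol formed, 1 mg protein, 30 min -> 1 U/mg
  expect_equal(specific_activity(0.3, cal, 1, 30), 1.0)
  expect_equal(specific_activity(0, cal, 1, 30), 0)
  # doubling protein halves specific activity
  expect_equal(specific_activity(0.3, cal, 2, 30),
               specific_activity(0.3, cal, 1, 30) / 2)
  # intercept is subtracted before conversion
  expect_equal(specific_activity(0.35, list(slope = 0.01, intercept = 0.05),
                                 1, 30), 1.0)
  expect_error(specific_activity(0.3, cal, 0, 30), "protein")
  expect_error(specific_activity(0.3, cal, 1, 0), "time")
  expect_error(specific_activity(0.3, list(slope = -1), 1, 30), "slope")
})
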