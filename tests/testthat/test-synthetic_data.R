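test_that("generators are bit-reproducible under a fixed seed", {
  for (p in c("table4-intrinsic", "fig5", "fig9-exp",
              "mixture-iap-dominant")) {
    sp <- preset(p, seed = 99)
    expect_identical(generate(sp), generate(sp))
  }
  a <- gen_kinetic(preset("table4-intrinsic", seed = 1))
  b <- gen_kinetic(preset("table4-intrinsic", seed = 2))
  expect_false(identical(a$activity, b$activity))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(gen_kinetic(preset("table4-intrinsic", seed = 5)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("noise-free generation followed by the matching fit closes the loop", {
  cases <- list(
    list(p = "table2-fraction1", fit = function(d) fit_michaelis_menten(d),
         truth = c(22.28, 89.26), get = function(f) c(f$Km, f$Vmax)),
    list(p = "table4-total", fit = function(d) fit_michaelis_menten(d),
         truth = c(3064.0, 1.64), get = function(f) c(f$Km, f$Vmax)),
    list(p = "fig5", fit = function(d) fit_sigmoid_dose_response(d),
         truth = c(1.98, 4.95, 4605, -0.002),
         get = function(f) c(f$Bo, f$To, f$ED50, f$hill)),
    list(p = "fig9-exp", fit = function(d) fit_exponential(d),
         truth = c(3.014, -0.0218), get = function(f) c(f$J0, f$b)),
    list(p = "fig8-quad", fit = function(d) fit_quadratic(d),
         truth = c(2.209, -0.064, 0.0007),
         get = function(f) c(f$c0, f$c1, f$c2)))
  for (cs in cases) {
    d <- generate(preset(cs$p, noise_sd = 0))
    f <- suppressWarnings(cs$fit(d))
    expect_equal(cs$get(f), cs$truth, tolerance = 1e-5,
                 label = cs$p)
  }
})

test_that("default grids mirror the two gradient designs", {
  d10 <- gen_kinetic(sim_spec("michaelis_menten",
                              list(Km = 50, Vmax = 10),
                              grid = apkin:::GRID_10_UM, replicates = 4))
  expect_equal(length(unique(d10$substrate_conc)), 10)
  expect_equal(range(d10$substrate_conc), c(0, 800))
  d16 <- gen_kinetic(preset("table4-intrinsic"))
  expect_equal(length(unique(d16$substrate_conc)), 16)
  expect_equal(range(d16$substrate_conc), c(0, 6000))
  expect_equal(nrow(d16), 64)
})

test_that("thermal-inhibition generation respects its own semantics", {
  expect_error(
    gen_thermal(sim_spec("thermal_inhibition",
                         list(I_C = 1, I_MAX = 1.2, TC50 = 30))),
    "I_MAX")
  # plateau at I_MIN = I_C - I_MAX for treatments far above TC50
  sp <- sim_spec("thermal_inhibition",
                 list(I_C = 1.36, I_MAX = 1.2, TC50 = 3),
                 grid = c(22, 90, 95, 100), noise_sd = 0)
  d <- gen_thermal(sp)
  expect_equal(d$activity[d$temperature == 22], 1.36)
  expect_lt(abs(d$activity[d$temperature == 100] - (1.36 - 1.2)), 0.05)
  expect_true(all(diff(d$activity) <= 0))

  # the generator satisfies the linearization exactly on the inhibition
  # scale: D = I_C - J regressed on D/I' recovers I_MAX and TC50
  d2 <- gen_thermal(sim_spec("thermal_inhibition",
                             list(I_C = 1.36, I_MAX = 1.2, TC50 = 31.12),
                             noise_sd = 0, replicates = 4))
  D <- 1.36 - d2$activity
  Ip <- d2$temperature - 22
  keep <- Ip > 0
  fit <- stats::lm(D[keep] ~ I(D[keep] / Ip[keep]))
  expect_equal(unname(stats::coef(fit)), c(1.2, -31.12), tolerance = 1e-8)
})

test_that("the published-procedure estimator runs on generated inhibition data", {
  # The J-on-J/I regression reproduces published tables from published
  # lines, but its slope only attenuatedly tracks the generating TC50 of
  # the saturating forward model; assert what holds: a significant,
  # positive, finite estimate below the generating value.
  set.seed(55)
  for (i in 1:10) {
    tc <- stats::runif(1, 20, 45)
    ic <- stats::runif(1, 1, 3)
    sp <- sim_spec("thermal_inhibition",
                   list(I_C = ic, I_MAX = 0.85 * ic, TC50 = tc),
                   noise_sd = 0, replicates = 4, seed = i)
    r <- suppressWarnings(estimate_thermal_params(gen_thermal(sp)))
    expect_false(r$ns_flag)
    expect_gt(r$TC50, 0)
    expect_lt(r$TC50, tc)
    expect_equal(r$I_MAX, r$I_C - r$I_MIN, tolerance = 1e-12)
  }
})

test_that("mixture generation honors the pure-isoform limits", {
  sp <- sim_spec("isozyme_mixture",
                 list(total = 30, f_iap = 1,
                      phi_phe = c(0.5, 0.9), phi_harg = c(0.5, 0.9),
                      concs = c(0, 10, 100)),
                 noise_sd = 0, replicates = 2)
  tab <- normalize_to_baseline(gen_isozyme_mixture(sp))
  phe <- tab[tab$inhibitor == "L-Phe" & tab$conc_mM == 100, ]
  harg <- tab[tab$inhibitor == "L-hArg" & tab$conc_mM == 100, ]
  expect_equal(phe$inhibited_pct, 90, tolerance = 1e-9)
  expect_equal(harg$inhibited_pct, 0, tolerance = 1e-9)

  # an even mixture under full selective inhibition loses half either way
  sp2 <- sim_spec("isozyme_mixture",
                  list(total = 10, f_iap = 0.5,
                       phi_phe = c(1, 1), phi_harg = c(1, 1)),
                  noise_sd = 0)
  tab2 <- normalize_to_baseline(gen_isozyme_mixture(sp2))
  expect_true(all(abs(tab2$inhibited_pct[tab2$conc_mM == 100] - 50) < 1e-9))
})

test_that("invalid simulation specs are refused", {
  expect_error(sim_spec("michaelis_menten", list(), noise_sd = -1), ">= 0")
  expect_error(sim_spec("michaelis_menten", list(), replicates = 0), ">= 1")
  expect_error(preset("no-such-preset"), "unknown preset")
  expect_error(gen_kinetic(sim_spec("michaelis_menten",
                                    list(Km = -5, Vmax = 1))), "> 0")
  expect_error(
    gen_isozyme_mixture(sim_spec("isozyme_mixture",
                                 list(total = 10, f_iap = 1.4,
                                      phi_phe = c(1, 1),
                                      phi_harg = c(1, 1)))),
    "f_iap")
  expect_error(
    gen_isozyme_mixture(sim_spec("isozyme_mixture",
                                 list(total = 10, f_iap = 0.5,
                                      phi_phe = c(2, 1),
                                      phi_harg = c(1, 1)))),
    "phi_phe")
})
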