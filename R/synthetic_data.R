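# Seeded synthetic-data generators.
#
# Every generator is bit-reproducible: the same spec and seed give the
# same dataset. The RNG state of the caller is preserved. Noise is
# additive Gaussian on the response scale (reported uncertainties in the
# emulated designs are symmetric +/- SE); preset noise_sd values are
# calibrated so simulated parameter SEs are of the same order as the
# published estimates' SEs.

# The two substrate-gradient designs: 10 levels over 0-0.8 mM and 16
# levels over 0-6 mM (uM internally), with geometric-ish spacing so each
# design brackets the half-saturation point of its target kinetics.
GRID_10_UM <- c(0, 6.25, 12.5, 25, 50, 100, 200, 400, 600, 800)
GRID_16_UM <- c(0, 25, 50, 100, 200, 400, 600, 800,
                1200, 1600, 2400, 3200, 4000, 4800, 5600, 6000)
# Dose levels of the deglycosylation dose-response design (U/mg protein).
DOSES_U_PER_MG <- c(0, 1430, 4289, 7150, 8579, 12868)
# Thermal treatment levels: room-temperature control to 80 C.
GRID_THERMAL_C <- c(22, 40, 50, 60, 70, 80)

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation specification
#'
#' @param model one of `"michaelis_menten"`, `"sigmoid_eq1"` (the
#'   four-parameter logistic), `"exponential_eq2"`, `"quadratic"`,
#'   `"thermal_inhibition"`, `"isozyme_mixture"`.
#' @param parameters named list of generating parameters (see the
#'   individual generators).
#' @param grid design points (substrate uM, dose, or temperature C,
#'   depending on the model); ignored by `isozyme_mixture`.
#' @param noise_sd response-scale Gaussian standard deviation, >= 0.
#' @param replicates replicate measurements per design point, >= 1.
#' @param seed integer seed; identical spec + seed gives an identical
#'   dataset.
#' @return Class `"sim_spec"`.
#' @export
sim_spec <- function(model, parameters, grid = NULL, noise_sd = 0,
                     replicates = 1L, seed = 1L) {
  model <- match.arg(model, c("michaelis_menten", "sigmoid_eq1",
                              "exponential_eq2", "quadratic",
                              "thermal_inhibition", "isozyme_mixture"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(grid) && length(grid) == 0) stop("grid must be non-empty")
  structure(list(model = model, parameters = parameters, grid = grid,
                 noise_sd = noise_sd, replicates = replicates,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.expand_grid_reps <- function(grid, replicates) {
  data.frame(x = rep(grid, each = replicates),
             replicate = rep(seq_len(replicates), times = length(grid)))
}

#' Generate a Michaelis-Menten kinetic dataset
#'
#' `v = Vmax*S/(Km+S) + N(0, noise_sd)` per replicate at each grid
#' substrate level.
#'
#' @param spec a [sim_spec()] with `model = "michaelis_menten"` and
#'   parameters `Km`, `Vmax` (both > 0). Default grid: the 16-level
#'   0-6 mM design.
#' @return A [kinetic_dataset()].
#' @export
gen_kinetic <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$model != "michaelis_menten") {
    stop("gen_kinetic requires model = 'michaelis_menten'")
  }
  p <- spec$parameters
  if (is.null(p$Km) || is.null(p$Vmax) || p$Km <= 0 || p$Vmax <= 0) {
    stop("parameters Km and Vmax must be supplied and > 0")
  }
  grid <- spec$grid %||% GRID_16_UM
  d <- .expand_grid_reps(grid, spec$replicates)
  v <- .with_seed(spec$seed, {
    eval_michaelis_menten(d$x, p$Km, p$Vmax) +
      stats::rnorm(nrow(d), 0, spec$noise_sd)
  })
  kinetic_dataset(d$x, v, replicate = d$replicate,
                  specimen_id = p$specimen_id %||% "sim",
                  condition = p$condition %||% "simulated", unit = "uM")
}

#' Generate a sigmoidal dose-response table
#'
#' Four-parameter logistic responses plus noise at the design doses
#' (default: the six-dose deglycosylation design).
#'
#' @param spec a [sim_spec()] with `model = "sigmoid_eq1"` and parameters
#'   `Bo`, `To`, `ED50`, `hill`.
#' @return data.frame with `dose_U_per_mg`, `activity`, `replicate`.
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$model != "sigmoid_eq1") {
    stop("gen_dose_response requires model = 'sigmoid_eq1'")
  }
  p <- spec$parameters
  need <- c("Bo", "To", "ED50", "hill")
  if (!all(need %in% names(p))) {
    stop("parameters Bo, To, ED50, hill must all be supplied")
  }
  grid <- spec$grid %||% DOSES_U_PER_MG
  d <- .expand_grid_reps(grid, spec$replicates)
  y <- .with_seed(spec$seed, {
    eval_sigmoid(d$x, p$Bo, p$To, p$ED50, p$hill) +
      stats::rnorm(nrow(d), 0, spec$noise_sd)
  })
  data.frame(dose_U_per_mg = d$x, activity = y, replicate = d$replicate)
}

#' Generate a thermal residual-activity series
#'
#' Three forward models over a 22-80 C grid:
#' * `exponential_eq2`: `J = J0 * exp(b * I)`;
#' * `quadratic`: `J = c0 + c1*I + c2*I^2`;
#' * `thermal_inhibition`: `J = I_C - I_MAX * I' / (TC50 + I')` with
#'   `I' = I - min(grid)`, a saturating-inhibition forward model
#'   consistent with the intended semantics of the Eadie-Hofstee-style
#'   estimator (a package construction: the linearization itself has no
#'   usable forward form). Requires `I_MAX <= I_C` so residual activity
#'   stays non-negative; the series plateaus at `I_C - I_MAX`.
#'
#' @param spec a [sim_spec()] with one of the three models above.
#' @return A [thermal_series()].
#' @export
gen_thermal <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  p <- spec$parameters
  grid <- spec$grid %||% GRID_THERMAL_C
  d <- .expand_grid_reps(grid, spec$replicates)
  mu <- switch(spec$model,
    exponential_eq2 = {
      if (is.null(p$J0) || is.null(p$b)) stop("J0 and b are required")
      p$J0 * exp(p$b * d$x)
    },
    quadratic = {
      if (!all(c("c0", "c1", "c2") %in% names(p))) {
        stop("c0, c1, c2 are required")
      }
      p$c0 + p$c1 * d$x + p$c2 * d$x^2
    },
    thermal_inhibition = {
      if (!all(c("I_C", "I_MAX", "TC50") %in% names(p))) {
        stop("I_C, I_MAX, TC50 are required")
      }
      if (p$I_MAX > p$I_C) {
        stop("I_MAX must not exceed I_C (residual activity would go negative)")
      }
      Iprime <- d$x - min(grid)
      p$I_C - p$I_MAX * Iprime / (p$TC50 + Iprime)
    },
    stop("gen_thermal requires an exponential_eq2, quadratic or thermal_inhibition spec"))
  y <- .with_seed(spec$seed, mu + stats::rnorm(nrow(d), 0, spec$noise_sd))
  thermal_series(d$x, y, is_relative = isTRUE(p$is_relative))
}

#' Generate a two-isoform inhibitor-fractionation activity table
#'
#' Emulates the selective-inhibitor design: a mixture of an IAP-like and
#' a TNAP-like component with total baseline activity `total` and IAP
#' fraction `f_iap`, measured under L-Phe (inhibits the IAP component by
#' fraction `phi_phe[c]`) and L-hArg (inhibits the TNAP component by
#' `phi_harg[c]`) at each concentration. Group means are
#' `total * (f_iap*(1 - phi_phe(c)) + (1 - f_iap))` for L-Phe and the
#' mirror for L-hArg, plus replicate noise. The 0-mM rows (no inhibition)
#' are included for both inhibitors.
#'
#' @param spec a [sim_spec()] with `model = "isozyme_mixture"` and
#'   parameters `total` (> 0), `f_iap` in `[0, 1]`, `phi_phe` and
#'   `phi_harg` (numeric vectors in `[0, 1]`, one value per non-zero
#'   concentration), `concs` (default `c(0, 10, 100)` mM).
#' @return data.frame with `inhibitor`, `conc_mM`, `activity`,
#'   `replicate` -- the raw table [normalize_to_baseline()] consumes.
#' @export
gen_isozyme_mixture <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$model != "isozyme_mixture") {
    stop("gen_isozyme_mixture requires model = 'isozyme_mixture'")
  }
  p <- spec$parameters
  concs <- p$concs %||% c(0, 10, 100)
  nz <- concs[concs > 0]
  if (is.null(p$f_iap) || p$f_iap < 0 || p$f_iap > 1) {
    stop("f_iap must lie in [0, 1]")
  }
  if (is.null(p$total) || p$total <= 0) stop("total must be > 0")
  for (nm in c("phi_phe", "phi_harg")) {
    phi <- p[[nm]]
    if (is.null(phi) || length(phi) != length(nz) ||
        any(phi < 0) || any(phi > 1)) {
      stop(sprintf("%s must give one value in [0, 1] per non-zero concentration",
                   nm))
    }
  }
  f_iap <- p$f_iap
  f_tnap <- 1 - f_iap
  mean_at <- function(inhibitor, conc) {
    if (conc == 0) return(p$total)
    i <- match(conc, nz)
    if (inhibitor == "L-Phe") {
      p$total * (f_iap * (1 - p$phi_phe[i]) + f_tnap)
    } else {
      p$total * (f_iap + f_tnap * (1 - p$phi_harg[i]))
    }
  }
  rows <- expand.grid(replicate = seq_len(spec$replicates),
                      conc_mM = concs,
                      inhibitor = c("L-Phe", "L-hArg"),
                      stringsAsFactors = FALSE)
  mu <- mapply(mean_at, rows$inhibitor, rows$conc_mM)
  act <- .with_seed(spec$seed,
                    mu + stats::rnorm(nrow(rows), 0, spec$noise_sd))
  data.frame(inhibitor = rows$inhibitor, conc_mM = rows$conc_mM,
             activity = act, replicate = rows$replicate,
             stringsAsFactors = FALSE)
}

# Preset generating parameters: the published point estimates of the
# designs the generators emulate. noise_sd values are fixed calibrations
# chosen so simulated parameter SEs are of the same order as the
# published SEs under each design.
.PRESETS <- list(
  `table2-fraction1` = list(model = "michaelis_menten",
    parameters = list(Km = 22.28, Vmax = 89.26),
    grid = GRID_10_UM, noise_sd = 13, replicates = 3L),
  `table2-fraction2` = list(model = "michaelis_menten",
    parameters = list(Km = 53.12, Vmax = 56.75),
    grid = GRID_10_UM, noise_sd = 5.5, replicates = 3L),
  `table2-fraction3` = list(model = "michaelis_menten",
    parameters = list(Km = 327.0, Vmax = 349.1),
    grid = GRID_10_UM, noise_sd = 9, replicates = 3L),
  `table2-fraction4` = list(model = "michaelis_menten",
    parameters = list(Km = 233.7, Vmax = 131.2),
    grid = GRID_10_UM, noise_sd = 4.6, replicates = 3L),
  `table4-total` = list(model = "michaelis_menten",
    parameters = list(Km = 3064.0, Vmax = 1.64),
    grid = GRID_16_UM, noise_sd = 0.07, replicates = 4L),
  `table4-intrinsic` = list(model = "michaelis_menten",
    parameters = list(Km = 4068.0, Vmax = 0.89),
    grid = GRID_16_UM, noise_sd = 0.035, replicates = 4L),
  `table4-partitioned` = list(model = "michaelis_menten",
    parameters = list(Km = 2102.0, Vmax = 0.75),
    grid = GRID_16_UM, noise_sd = 0.075, replicates = 4L),
  fig5 = list(model = "sigmoid_eq1",
    parameters = list(Bo = 1.98, To = 4.95, ED50 = 4605, hill = -0.002),
    grid = DOSES_U_PER_MG, noise_sd = 0.55, replicates = 4L),
  `fig8-quad` = list(model = "quadratic",
    parameters = list(c0 = 2.209, c1 = -0.064, c2 = 0.0007),
    grid = GRID_THERMAL_C, noise_sd = 0.13, replicates = 4L),
  `fig9-exp` = list(model = "exponential_eq2",
    parameters = list(J0 = 3.014, b = -0.0218),
    grid = GRID_THERMAL_C, noise_sd = 0.65, replicates = 4L),
  `thermal-inhibition` = list(model = "thermal_inhibition",
    parameters = list(I_C = 1.36, I_MAX = 1.20, TC50 = 31.12),
    grid = GRID_THERMAL_C, noise_sd = 0.12, replicates = 4L),
  `mixture-iap-dominant` = list(model = "isozyme_mixture",
    parameters = list(total = 30.64, f_iap = 0.85,
                      phi_phe = c(0.9, 1.0), phi_harg = c(0.2, 1.0),
                      concs = c(0, 10, 100)),
    grid = NULL, noise_sd = 3.3, replicates = 4L),
  `mixture-tnap-dominant` = list(model = "isozyme_mixture",
    parameters = list(total = 11.63, f_iap = 0.15,
                      phi_phe = c(0.2, 1.0), phi_harg = c(0.9, 1.0),
                      concs = c(0, 10, 100)),
    grid = NULL, noise_sd = 1.3, replicates = 4L),
  `mixture-mixed` = list(model = "isozyme_mixture",
    parameters = list(total = 5.76, f_iap = 0.5,
                      phi_phe = c(0.3, 0.6), phi_harg = c(0.3, 0.6),
                      concs = c(0, 10, 100)),
    grid = NULL, noise_sd = 0.65, replicates = 4L)
)

#' Named simulation presets
#'
#' Presets embed the published point estimates for each emulated design:
#' the four purified jejunal IAP fractions on the 10-level gradient, the
#' total and intrinsic lysate kinetics on the 16-level gradient, the
#' deglycosylation dose-response sigmoid, the quadratic and exponential
#' thermal responses, a saturating thermal-inhibition curve, and
#' two-isoform inhibitor mixtures.
#'
#' @param name preset name; see `names(apkin:::.PRESETS)` or call
#'   [preset_names()].
#' @param seed integer seed for the returned spec.
#' @param noise_sd optional override of the preset's calibrated noise.
#' @param replicates optional override of the preset's replicate count.
#' @return A [sim_spec()].
#' @export
preset <- function(name, seed = 1L, noise_sd = NULL, replicates = NULL) {
  if (!name %in% names(.PRESETS)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(.PRESETS), collapse = ", ")))
  }
  p <- .PRESETS[[name]]
  sim_spec(model = p$model, parameters = p$parameters, grid = p$grid,
           noise_sd = noise_sd %||% p$noise_sd,
           replicates = replicates %||% p$replicates, seed = seed)
}

#' @rdname preset
#' @export
preset_names <- function() names(.PRESETS)

#' Dispatch a simulation spec to its generator
#'
#' @param spec a [sim_spec()].
#' @return The generated dataset (type depends on the model).
#' @export
generate <- function(spec) {
  switch(spec$model,
         michaelis_menten = gen_kinetic(spec),
         sigmoid_eq1 = gen_dose_response(spec),
         isozyme_mixture = gen_isozyme_mixture(spec),
         gen_thermal(spec))
}
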