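# Declarative multi-stage pipeline: simulate / load inputs, fit, partition,
# estimate thermostability, fractionate and compare, with every stage's
# result persisted as key-sorted structured text and hashed into a
# manifest. Re-running with identical config and seed reproduces the
# manifest bit-exactly.

.stage_to_result <- function(type, obj, provenance) {
  pse <- function(est, se) list(estimate = est, se = se)
  switch(type,
    fit_mm = analysis_result("fit_michaelis_menten",
      parameters = list(Km = pse(obj$Km, obj$se_Km),
                        Vmax = pse(obj$Vmax, obj$se_Vmax)),
      diagnostics = list(r_squared = obj$r_squared, n = obj$n,
                         df = obj$df,
                         use_replicate_means = obj$use_replicate_means),
      provenance = provenance),
    fit_sigmoid = analysis_result("fit_sigmoid_dose_response",
      parameters = list(Bo = pse(obj$Bo, obj$se_Bo),
                        To = pse(obj$To, obj$se_To),
                        ED50 = pse(obj$ED50, obj$se_ED50),
                        hill = pse(obj$hill, obj$se_hill)),
      diagnostics = list(r_squared = obj$r_squared, n = obj$n,
                         ed50_in_range = obj$ed50_in_range),
      provenance = provenance),
    fit_thermal_quad = analysis_result("fit_quadratic",
      parameters = list(c0 = pse(obj$c0, obj$se_c0),
                        c1 = pse(obj$c1, obj$se_c1),
                        c2 = pse(obj$c2, obj$se_c2)),
      diagnostics = list(r_squared = obj$r_squared, n = obj$n),
      provenance = provenance),
    fit_thermal_exp = analysis_result("fit_exponential",
      parameters = list(J0 = pse(obj$J0, obj$se_J0),
                        b = pse(obj$b, obj$se_b)),
      diagnostics = list(r_squared = obj$r_squared, n = obj$n),
      provenance = provenance),
    thermostability = as_analysis_result(obj, provenance = provenance),
    partition = analysis_result("partition_parameters",
      parameters = list(Vmax = pse(obj$Vmax, obj$se_Vmax)),
      diagnostics = list(method = obj$method),
      provenance = provenance),
    inhibition = analysis_result("classify_isoform_dominance",
      parameters = list(),
      diagnostics = list(label = obj$label,
                         n_rows = nrow(obj$table)),
      provenance = provenance),
    compare = analysis_result("pooled_estimate_ttest",
      parameters = list(),
      diagnostics = list(t = obj$t, df = obj$df, p = obj$p,
                         significant = obj$significant,
                         trend = obj$trend),
      provenance = provenance),
    stop(sprintf("no result mapping for stage type '%s'", type)))
}

.pipeline_get <- function(store, name, stage_name) {
  if (!name %in% names(store)) {
    stop(sprintf("stage '%s' refers to unknown step '%s'",
                 stage_name, name))
  }
  store[[name]]
}

#' Run a declarative analysis pipeline
#'
#' Executes named stages in declared order. Each stage's structured
#' result is written to `<out_dir>/<stage-name>.json` (key-sorted, full
#' precision) and its md5 hash recorded in the manifest; identical
#' config + seed reproduces identical hashes. A failing stage stops the
#' pipeline with the stage name in the error; prior outputs are left
#' intact.
#'
#' Stage types and their fields (all stages need `name` and `type`):
#' \describe{
#'   \item{simulate}{`preset` (see [preset()]) or full [sim_spec()]
#'     fields; optional `seed` (defaults to the config seed).}
#'   \item{read}{`path` and `schema` for [read_assay_table()].}
#'   \item{fit_mm}{`input` (a dataset stage); optional
#'     `use_replicate_means`.}
#'   \item{fit_sigmoid}{`input` (a dose-response stage).}
#'   \item{fit_thermal}{`input` (a thermal stage); `model` `"quad"` or
#'     `"exp"`.}
#'   \item{thermostability}{`input` (a thermal stage); optional
#'     `control_activity`.}
#'   \item{partition}{`total` and `background`; `method`
#'     `"params"` (two fit stages) or `"pointwise"` (two dataset
#'     stages).}
#'   \item{inhibition}{`input` (a raw inhibitor activity table stage);
#'     optional `threshold`.}
#'   \item{compare}{`a`, `b` (fit stages), `param` (`"Km"` or
#'     `"Vmax"`).}
#' }
#'
#' @param config a named list with `steps` (list of stage specs), and
#'   optionally `seed` (default 1), `out_dir` (default `tempdir()`
#'   subdirectory), `alpha` (significance, default 0.05), `trend_alpha`
#'   (default 0.10); or the path to a YAML file with those keys.
#' @return list with `manifest` (data.frame: stage, type, file, md5) and
#'   `objects` (named list of in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$steps) || length(config$steps) == 0) {
    stop("config must declare at least one step")
  }
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  trend_alpha <- config$trend_alpha %||% 0.10
  if (alpha <= 0 || alpha >= 1 || trend_alpha <= 0 || trend_alpha >= 1) {
    stop("significance thresholds must lie in (0, 1)")
  }
  out_dir <- config$out_dir %||% file.path(tempdir(), "apkin-pipeline")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nm <- vapply(config$steps, function(s) s$name %||% "", character(1))
  if (any(nm == "") || anyDuplicated(nm)) {
    stop("every step needs a unique 'name'")
  }

  store <- list()
  manifest <- data.frame(stage = character(0), type = character(0),
                         file = character(0), md5 = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(config$steps)) {
    step <- config$steps[[i]]
    type <- step$type %||% stop(sprintf("step '%s' has no type", nm[i]))
    prov <- list(seed = seed, stage_index = i)
    obj <- tryCatch(switch(type,
      simulate = {
        sp <- if (!is.null(step$preset)) {
          preset(step$preset, seed = step$seed %||% seed,
                 noise_sd = step$noise_sd, replicates = step$replicates)
        } else {
          sim_spec(model = step$model, parameters = step$parameters,
                   grid = step$grid, noise_sd = step$noise_sd %||% 0,
                   replicates = step$replicates %||% 1L,
                   seed = step$seed %||% seed)
        }
        generate(sp)
      },
      read = read_assay_table(step$path, schema = step$schema),
      fit_mm = fit_michaelis_menten(
        .pipeline_get(store, step$input, nm[i]),
        use_replicate_means = isTRUE(step$use_replicate_means)),
      fit_sigmoid = fit_sigmoid_dose_response(
        .pipeline_get(store, step$input, nm[i])),
      fit_thermal = {
        dat <- .pipeline_get(store, step$input, nm[i])
        if (identical(step$model, "exp")) fit_exponential(dat)
        else fit_quadratic(dat)
      },
      thermostability = estimate_thermal_params(
        .pipeline_get(store, step$input, nm[i]),
        control_activity = step$control_activity, alpha = alpha),
      partition = {
        if (identical(step$method, "pointwise")) {
          partition_pointwise(.pipeline_get(store, step$total, nm[i]),
                              .pipeline_get(store, step$background, nm[i]))
        } else {
          partition_parameters(.pipeline_get(store, step$total, nm[i]),
                               .pipeline_get(store, step$background, nm[i]))
        }
      },
      inhibition = {
        tbl <- normalize_to_baseline(
          .pipeline_get(store, step$input, nm[i]))
        list(table = tbl,
             label = classify_isoform_dominance(
               tbl, threshold = step$threshold %||% 50))
      },
      compare = {
        pick <- function(fit, param) {
          estimate_with_se(fit[[param]], fit[[paste0("se_", param)]],
                           df = fit$df %||% (fit$n - 2L))
        }
        a <- pick(.pipeline_get(store, step$a, nm[i]), step$param)
        b <- pick(.pipeline_get(store, step$b, nm[i]), step$param)
        pooled_estimate_ttest(a, b, alpha = alpha, trend = trend_alpha)
      },
      stop(sprintf("unknown stage type '%s'", type))
    ), error = function(e) {
      stop(sprintf("pipeline stage '%s' (%s) failed: %s",
                   nm[i], type, conditionMessage(e)), call. = FALSE)
    })
    store[[nm[i]]] <- obj

    res_type <- if (type == "fit_thermal") {
      if (identical(step$model, "exp")) "fit_thermal_exp"
      else "fit_thermal_quad"
    } else type
    persistable <- !res_type %in% c("simulate", "read") &&
      !(res_type == "partition" && identical(step$method, "pointwise"))
    if (persistable) {
      res <- .stage_to_result(res_type, obj, prov)
      path <- file.path(out_dir, paste0(nm[i], ".json"))
      write_result(res, path)
      manifest <- rbind(manifest, data.frame(
        stage = nm[i], type = type, file = path,
        md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
    }
  }
  list(manifest = manifest, objects = store)
}
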