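# Data model and delimited-table I/O shared by all analysis stages.
#
# Unit convention: substrate concentrations are stored internally in uM
# (micromolar). Tables supplied in mM are converted on ingestion (x 1000).
# Activities are specific activities in nmol/(mg protein.min) unless a
# series is flagged as percent-of-control (`is_relative`).

SCHEMA_VERSION <- "1.0"

.substrate_unit_factor <- function(unit) {
  switch(match.arg(unit, c("uM", "mM")), uM = 1, mM = 1000)
}

#' Construct a kinetic dataset
#'
#' A kinetic dataset holds replicate substrate-vs-velocity measurements for
#' one specimen/condition. Substrate concentrations are normalized to uM on
#' construction; normalization is idempotent (a dataset already in uM is
#' left untouched).
#'
#' @param substrate_conc numeric vector of substrate concentrations (>= 0).
#' @param activity numeric vector of specific activities in
#'   nmol/(mg protein.min). May contain any real value: enhancement above a
#'   control is legal.
#' @param replicate positive integer replicate index (recycled).
#' @param specimen_id,condition identifier strings (recycled).
#' @param unit unit of `substrate_conc`: `"uM"` (default) or `"mM"`.
#' @return A `data.frame` of class `"kinetic_dataset"` with columns
#'   `specimen_id`, `condition`, `substrate_conc` (uM), `activity`,
#'   `replicate`, and attribute `substrate_unit = "uM"`.
#' @export
kinetic_dataset <- function(substrate_conc, activity, replicate = 1L,
                            specimen_id = "specimen", condition = "none",
                            unit = c("uM", "mM")) {
  unit <- match.arg(unit)
  if (length(substrate_conc) != length(activity)) {
    stop("substrate_conc and activity must have the same length")
  }
  if (any(!is.finite(substrate_conc)) || any(substrate_conc < 0)) {
    stop("substrate concentrations must be finite and >= 0")
  }
  if (any(!is.finite(activity))) stop("activities must be finite")
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate indices must be >= 1")
  out <- data.frame(
    specimen_id = as.character(specimen_id),
    condition = as.character(condition),
    substrate_conc = substrate_conc * .substrate_unit_factor(unit),
    activity = activity,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("kinetic_dataset", "data.frame")
  attr(out, "substrate_unit") <- "uM"
  out
}

#' Construct a thermal residual-activity series
#'
#' @param temperature temperatures in Celsius, within `[0, 100]`.
#' @param activity residual activities, either specific activities or
#'   percent-of-control (see `is_relative`).
#' @param is_relative logical; `TRUE` when `activity` is percent of the
#'   control (lowest-temperature) group.
#' @return A `data.frame` of class `"thermal_series"` with attribute
#'   `is_relative`.
#' @export
thermal_series <- function(temperature, activity, is_relative = FALSE) {
  if (length(temperature) != length(activity)) {
    stop("temperature and activity must have the same length")
  }
  if (any(!is.finite(temperature)) || any(temperature < 0) ||
      any(temperature > 100)) {
    stop("temperatures must lie within [0, 100] degrees C")
  }
  if (any(!is.finite(activity))) stop("activities must be finite")
  out <- data.frame(temperature = temperature, activity = activity)
  class(out) <- c("thermal_series", "data.frame")
  attr(out, "is_relative") <- isTRUE(is_relative)
  out
}

#' Control temperature of a thermal series
#'
#' The control group is the lowest temperature present (22 C in the
#' reference design).
#' @param series a `thermal_series`.
#' @return The control temperature (scalar).
#' @export
control_temperature <- function(series) min(series$temperature)

# Mandatory columns per CSV schema. `substrate_conc` may be spelled with a
# unit suffix (`substrate_conc_uM` / `substrate_conc_mM`), which fixes the
# ingestion unit.
.schema_columns <- list(
  kinetic = c("substrate_conc", "activity"),
  dose_response = c("dose_U_per_mg", "activity"),
  thermal = c("temperature_C", "activity"),
  inhibition = c("inhibitor", "conc_mM", "activity")
)

.resolve_substrate_column <- function(nm) {
  hits <- intersect(c("substrate_conc", "substrate_conc_uM",
                      "substrate_conc_mM"), nm)
  if (length(hits) == 0) return(NULL)
  hits[[1]]
}

.check_numeric_column <- function(raw, col, path) {
  vals <- raw[[col]]
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num) & !is.na(vals) & trimws(as.character(vals)) != "")
  if (length(bad) > 0) {
    stop(sprintf(
      "non-numeric value(s) in column '%s' of '%s' at data row(s) %s",
      col, path, paste(bad, collapse = ", ")))
  }
  if (anyNA(num)) {
    stop(sprintf("missing value(s) in column '%s' of '%s' at data row(s) %s",
                 col, path, paste(which(is.na(num)), collapse = ", ")))
  }
  num
}

#' Read an assay table from CSV
#'
#' Reads one of the four delimited assay-table schemas and returns the
#' corresponding typed dataset with units normalized (substrate
#' concentrations in uM internally). Row order is preserved.
#'
#' Schemas (mandatory columns):
#' \describe{
#'   \item{kinetic}{`substrate_conc` (or `substrate_conc_uM` /
#'     `substrate_conc_mM`), `activity`; optional `specimen_id`,
#'     `condition`, `replicate`.}
#'   \item{dose_response}{`dose_U_per_mg`, `activity`.}
#'   \item{thermal}{`temperature_C`, `activity`; optional `is_relative`.}
#'   \item{inhibition}{`inhibitor`, `conc_mM`, `activity`; optional
#'     `replicate`, `segment`.}
#' }
#'
#' @param path path to a comma-separated file with a header row.
#' @param schema one of `"kinetic"`, `"dose_response"`, `"thermal"`,
#'   `"inhibition"`.
#' @param unit ingestion unit for a bare `substrate_conc` column
#'   (`"uM"` default); ignored when the column name carries a suffix.
#' @return A `kinetic_dataset`, `thermal_series`, or plain `data.frame`
#'   depending on the schema.
#' @export
read_assay_table <- function(path,
                             schema = c("kinetic", "dose_response",
                                        "thermal", "inhibition"),
                             unit = c("uM", "mM")) {
  schema <- match.arg(schema)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop(sprintf("empty table: '%s'", path))
  required <- .schema_columns[[schema]]

  if (schema == "kinetic") {
    scol <- .resolve_substrate_column(names(raw))
    if (is.null(scol)) {
      stop(sprintf("schema 'kinetic' requires column 'substrate_conc' %s",
                   sprintf("(missing in '%s')", path)))
    }
    if (scol == "substrate_conc_mM") unit <- "mM"
    if (scol == "substrate_conc_uM") unit <- "uM"
    required <- setdiff(required, "substrate_conc")
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("schema '%s' requires column(s) %s (missing in '%s')",
                 schema, paste(sprintf("'%s'", missing), collapse = ", "),
                 path))
  }

  switch(schema,
    kinetic = {
      s <- .check_numeric_column(raw, scol, path)
      v <- .check_numeric_column(raw, "activity", path)
      rep_ <- if ("replicate" %in% names(raw)) {
        as.integer(.check_numeric_column(raw, "replicate", path))
      } else 1L
      kinetic_dataset(
        substrate_conc = s, activity = v, replicate = rep_,
        specimen_id = if ("specimen_id" %in% names(raw)) raw$specimen_id
                      else "specimen",
        condition = if ("condition" %in% names(raw)) raw$condition
                    else "none",
        unit = unit)
    },
    dose_response = {
      data.frame(
        dose_U_per_mg = .check_numeric_column(raw, "dose_U_per_mg", path),
        activity = .check_numeric_column(raw, "activity", path))
    },
    thermal = {
      rel <- "is_relative" %in% names(raw) &&
        any(tolower(raw$is_relative) %in% c("true", "1", "yes"))
      thermal_series(.check_numeric_column(raw, "temperature_C", path),
                     .check_numeric_column(raw, "activity", path),
                     is_relative = rel)
    },
    inhibition = {
      out <- data.frame(
        inhibitor = raw$inhibitor,
        conc_mM = .check_numeric_column(raw, "conc_mM", path),
        activity = .check_numeric_column(raw, "activity", path),
        stringsAsFactors = FALSE)
      if ("replicate" %in% names(raw)) {
        out$replicate <- as.integer(.check_numeric_column(raw, "replicate",
                                                          path))
      }
      if ("segment" %in% names(raw)) out$segment <- raw$segment
      out
    })
}

#' Construct an analysis result
#'
#' The shared result container for every fitted stage: named parameter
#' estimates with standard errors (or an explicit `"NS"` marker, never a
#' silent absence), free-form diagnostics, and provenance.
#'
#' @param stage stage name (e.g. `"fit_michaelis_menten"`).
#' @param parameters named list; each element either
#'   `list(estimate =, se =)` or the string `"NS"`.
#' @param diagnostics named list of scalar diagnostics (R^2, p-values, n,
#'   df, ...).
#' @param provenance named list (input digest, seed, package version, ...).
#' @return An object of class `"analysis_result"`.
#' @export
analysis_result <- function(stage, parameters = list(),
                            diagnostics = list(), provenance = list()) {
  stopifnot(is.character(stage), length(stage) == 1)
  for (nm in names(parameters)) {
    p <- parameters[[nm]]
    ok <- (is.character(p) && identical(p, "NS")) ||
      (is.list(p) && all(c("estimate", "se") %in% names(p)) &&
         is.finite(p$estimate))
    if (!ok) {
      stop(sprintf(
        "parameter '%s' must be list(estimate=, se=) with finite estimate, or the marker \"NS\"",
        nm))
    }
  }
  provenance$package_version <-
    provenance$package_version %||% as.character(utils::packageVersion("apkin"))
  structure(
    list(schema_version = SCHEMA_VERSION, stage = stage,
         parameters = parameters, diagnostics = diagnostics,
         provenance = provenance),
    class = "analysis_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursively sort names so serialization is deterministic.
.sort_named <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x) > 0) x <- x[order(names(x))]
    x <- lapply(x, .sort_named)
  }
  x
}

#' Serialize an analysis result to structured text
#'
#' Writes a key-sorted JSON serialization. Two serializations of the same
#' result are byte-identical, and [read_result()] reproduces the result
#' exactly (full double precision is retained).
#'
#' @param result an [analysis_result()].
#' @param path output file path.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "analysis_result"))
  body <- .sort_named(unclass(result))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a serialized analysis result
#'
#' @param path a file written by [write_result()].
#' @return An `analysis_result`.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  analysis_result(stage = x$stage,
                  parameters = x$parameters %||% list(),
                  diagnostics = x$diagnostics %||% list(),
                  provenance = x$provenance %||% list())
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> stage: %s\n", x$stage))
  for (nm in names(x$parameters)) {
    p <- x$parameters[[nm]]
    if (identical(p, "NS")) {
      cat(sprintf("  %-12s NS\n", nm))
    } else {
      cat(sprintf("  %-12s %g (SE %g)\n", nm, p$estimate, p$se))
    }
  }
  if (length(x$diagnostics) > 0) {
    d <- vapply(x$diagnostics, function(v) paste(format(v), collapse = ","),
                character(1))
    cat("  diagnostics:", paste(sprintf("%s=%s", names(d), d),
                                collapse = ", "), "\n")
  }
  invisible(x)
}
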