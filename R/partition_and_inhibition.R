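# Partitioning isoform-specific kinetics out of lysate mixtures, and
# inhibitor-based isoform fractionation.
#
# Two partitioning routes are provided and labeled:
#   pointwise            per-substrate-level activity difference
#                        (total lysate - background lysate), then refit;
#   parameter_difference Vmax_total - Vmax_background with quadrature SE.
# The difference of two Michaelis-Menten curves is not itself exactly
# Michaelis-Menten, so a refit of the pointwise difference is an
# approximation; both routes are exposed so their estimates can be
# compared.

#' Point-wise partition of a kinetic dataset
#'
#' Subtracts background (e.g. vector-only lysate) activity from total
#' (e.g. isoform-overexpressing lysate) activity at each substrate level.
#' Both datasets must share an identical substrate grid. Per-level
#' replicate means are differenced; negative differences are preserved
#' (clipping them would bias a subsequent fit) and flagged with a warning.
#'
#' @param total,background [kinetic_dataset()] objects on the same
#'   substrate grid (uM).
#' @return A [kinetic_dataset()] of per-level mean differences (one row
#'   per substrate level), condition `"partitioned"`, with attribute
#'   `negative_differences` giving the count of negative values.
#' @export
partition_pointwise <- function(total, background) {
  gt <- sort(unique(total$substrate_conc))
  gb <- sort(unique(background$substrate_conc))
  if (length(gt) != length(gb) || any(gt != gb)) {
    unmatched <- union(setdiff(gt, gb), setdiff(gb, gt))
    stop(sprintf("substrate grids differ; unmatched concentration(s): %s",
                 paste(format(unmatched), collapse = ", ")))
  }
  mt <- tapply(total$activity, total$substrate_conc, mean)
  mb <- tapply(background$activity, background$substrate_conc, mean)
  S <- as.numeric(names(mt))
  diff_v <- as.numeric(mt) - as.numeric(mb)[match(names(mt), names(mb))]
  n_neg <- sum(diff_v < 0)
  if (n_neg > 0) {
    warning(sprintf(
      "%d negative partitioned difference(s) retained (not clipped)",
      n_neg))
  }
  out <- kinetic_dataset(S, diff_v,
                         specimen_id = total$specimen_id[1],
                         condition = "partitioned", unit = "uM")
  attr(out, "negative_differences") <- n_neg
  out
}

#' Parameter-difference partition of maximal activity
#'
#' `Vmax_specific = Vmax_total - Vmax_background`, with standard error by
#' quadrature, `sqrt(se_total^2 + se_background^2)`.
#'
#' @param total,background `"mm_fit"` objects (see
#'   [fit_michaelis_menten()]) or lists with `Vmax`, `se_Vmax` and
#'   `converged`.
#' @return list with `Vmax`, `se_Vmax`, `method = "parameter_difference"`.
#' @export
partition_parameters <- function(total, background) {
  for (f in list(total, background)) {
    if (!is.null(f$converged) && !isTRUE(f$converged)) {
      stop("both input fits must have converged")
    }
    if (is.null(f$Vmax)) stop("inputs must carry a Vmax estimate")
  }
  se_t <- total$se_Vmax %||% 0
  se_b <- background$se_Vmax %||% 0
  list(Vmax = total$Vmax - background$Vmax,
       se_Vmax = sqrt(se_t^2 + se_b^2),
       method = "parameter_difference")
}

#' Percent inhibition relative to a baseline
#'
#' `100 * (baseline - residual) / baseline`. Negative values (activity
#' enhancement above the baseline) are legal and flagged with a warning.
#'
#' @param baseline baseline (0-mM inhibitor) activity, > 0.
#' @param residual residual activity under the inhibitor.
#' @export
percent_inhibition <- function(baseline, residual) {
  if (any(baseline <= 0)) stop("baseline activity must be > 0")
  out <- 100 * (baseline - residual) / baseline
  if (any(out < 0)) warning("negative inhibition (enhancement) observed")
  out
}

#' Normalize inhibitor-group activities to the 0-mM baseline
#'
#' Group mean activities per inhibitor x concentration are expressed as a
#' percent of the 0-mM baseline mean (the no-inhibitor control, taken as
#' 100%). The baseline is shared across inhibitors within a segment: all
#' rows at 0 mM contribute to it. `inhibited_pct = 100 - residual_pct` in
#' every row by construction.
#'
#' @param groups data.frame with columns `inhibitor`, `conc_mM`,
#'   `activity` (replicate rows allowed) and optionally `segment`.
#' @return An inhibition table (class `"inhibition_table"`): one row per
#'   (segment x) inhibitor x concentration with `mean_activity`,
#'   `residual_pct`, `inhibited_pct`.
#' @export
normalize_to_baseline <- function(groups) {
  req <- c("inhibitor", "conc_mM", "activity")
  if (!all(req %in% names(groups))) {
    stop("groups must have columns inhibitor, conc_mM, activity")
  }
  if (!"segment" %in% names(groups)) groups$segment <- "all"
  pieces <- lapply(split(groups, groups$segment), function(g) {
    base_rows <- g$conc_mM == 0
    if (!any(base_rows)) {
      stop(sprintf("no 0-mM baseline group in segment '%s'",
                   g$segment[1]))
    }
    base_mean <- mean(g$activity[base_rows])
    if (base_mean <= 0) {
      stop(sprintf("baseline mean must be > 0 in segment '%s'",
                   g$segment[1]))
    }
    agg <- stats::aggregate(activity ~ inhibitor + conc_mM, data = g,
                            FUN = mean)
    names(agg)[names(agg) == "activity"] <- "mean_activity"
    agg$residual_pct <- ifelse(agg$conc_mM == 0, 100,
                               100 * agg$mean_activity / base_mean)
    agg$inhibited_pct <- 100 - agg$residual_pct
    agg$segment <- g$segment[1]
    agg[order(agg$inhibitor, agg$conc_mM),
        c("segment", "inhibitor", "conc_mM", "mean_activity",
          "residual_pct", "inhibited_pct")]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("inhibition_table", "data.frame")
  out
}

#' Classify isoform dominance from an inhibition table
#'
#' Uses the selective inhibitors at their top concentration: L-Phe
#' (IAP-selective) and L-hArg (TNAP-selective). A segment is IAP-dominant
#' when L-Phe inhibition is at least `threshold` while L-hArg inhibition
#' stays below it; TNAP-dominant in the mirror case; mixed otherwise.
#'
#' @param table an [normalize_to_baseline()] inhibition table containing
#'   both inhibitors at the top concentration (one segment).
#' @param threshold percent inhibition cutoff (default 50).
#' @param top_conc concentration (mM) at which to classify; defaults to
#'   the maximum concentration present.
#' @return `"IAP-dominant"`, `"TNAP-dominant"` or `"mixed"`.
#' @export
classify_isoform_dominance <- function(table, threshold = 50,
                                       top_conc = NULL) {
  if (is.null(top_conc)) top_conc <- max(table$conc_mM)
  pick <- function(inh) {
    rows <- table$inhibitor == inh & table$conc_mM == top_conc
    if (!any(rows)) {
      stop(sprintf("inhibitor '%s' missing at %g mM", inh, top_conc))
    }
    mean(table$inhibited_pct[rows])
  }
  phe <- pick("L-Phe")
  harg <- pick("L-hArg")
  if (phe >= threshold && harg < threshold) "IAP-dominant"
  else if (harg >= threshold && phe < threshold) "TNAP-dominant"
  else "mixed"
}
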