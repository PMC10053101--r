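# Comparison conventions for kinetic parameter estimates: fold difference,
# percent change, a pooled two-tailed t-test on estimates with standard
# errors, and one-way ANOVA with Tukey multiple comparisons.

#' Round half away from zero
#'
#' Prose-style rounding (2.5 -> 3, -2.5 -> -3), unlike R's banker's
#' rounding, for reporting integer percentages and one-decimal folds.
#' @param x numeric.
#' @param digits decimal digits (default 0).
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fold difference between two positive quantities
#'
#' Default convention is excess over baseline:
#' `(max(a, b) - min(a, b)) / min(a, b)`, i.e. a 6.4-fold difference means
#' the larger value is 7.4 times the smaller. The plain ratio
#' `max / min` is also available but is not the default. The direction
#' (whether `a` is higher or lower than `b`) is returned as an attribute
#' rather than folded into the number.
#'
#' @param a,b positive scalars.
#' @param convention `"excess"` (default) or `"ratio"`.
#' @return The fold value, with attribute `direction` (`"higher"`,
#'   `"lower"` or `"equal"`, describing `a` relative to `b`).
#' @export
fold_difference <- function(a, b, convention = c("excess", "ratio")) {
  convention <- match.arg(convention)
  if (a <= 0 || b <= 0) stop("fold difference requires positive inputs")
  hi <- max(a, b); lo <- min(a, b)
  out <- switch(convention, excess = (hi - lo) / lo, ratio = hi / lo)
  attr(out, "direction") <- if (a > b) "higher"
                            else if (a < b) "lower" else "equal"
  out
}

#' Percent change between a reference and a new value
#'
#' `increase`: `100 * (new / reference - 1)` (agrees with the excess-fold
#' convention: increase% = 100 * fold when `new > reference`).
#' `reduction`: `100 * (reference - new) / reference`.
#'
#' @param reference positive reference value(s).
#' @param new new value(s).
#' @param mode `"increase"` or `"reduction"`.
#' @export
percent_change <- function(reference, new,
                           mode = c("increase", "reduction")) {
  mode <- match.arg(mode)
  if (any(reference <= 0)) stop("reference must be > 0")
  switch(mode,
         increase = 100 * (new / reference - 1),
         reduction = 100 * (reference - new) / reference)
}

#' Bundle an estimate with its standard error and degrees of freedom
#'
#' @param value estimate.
#' @param se standard error, >= 0.
#' @param df degrees of freedom used in testing, >= 1. For a parameter
#'   estimate from a fit, `n - p` (observations minus fitted parameters).
#' @export
estimate_with_se <- function(value, se, df) {
  stopifnot(is.finite(value), is.finite(se), se >= 0, df >= 1)
  structure(list(value = value, se = se, df = as.integer(df)),
            class = "estimate_with_se")
}

#' Pooled two-tailed t-test on two parameter estimates
#'
#' `t = (a - b) / sqrt(se_a^2 + se_b^2)`, two-tailed p from the t
#' distribution with the conservative `df = min(df_a, df_b)`. Degenerate
#' zero-SE inputs give p = 1 for equal values and p = 0 (flagged) for
#' unequal values.
#'
#' @param a,b [estimate_with_se()] objects (or lists with `value`, `se`,
#'   `df`).
#' @param alpha significance threshold (default 0.05).
#' @param trend trend threshold (default 0.10).
#' @return list with `t`, `df`, `p`, `significant`, `trend`,
#'   `degenerate`.
#' @export
pooled_estimate_ttest <- function(a, b, alpha = 0.05, trend = 0.10) {
  se2 <- a$se^2 + b$se^2
  diff <- a$value - b$value
  df <- min(a$df, b$df)
  if (se2 == 0) {
    p <- if (diff == 0) 1 else 0
    return(list(t = if (diff == 0) 0 else Inf * sign(diff), df = df,
                p = p, significant = p < alpha, trend = p < trend,
                degenerate = TRUE))
  }
  tstat <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(t = tstat, df = df, p = p, significant = p < alpha,
       trend = p < trend, degenerate = FALSE)
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' Fits `aov(value ~ group)`, reports the F test, Tukey HSD adjusted
#' p-values per pair, and a compact letter display (groups sharing a
#' letter do not differ at `alpha`), mirroring the superscript convention
#' of kinetics tables.
#'
#' @param groups a named list of replicate numeric vectors (one per
#'   group, each of length >= 2), or a data.frame with columns `value`
#'   and `group`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `F`, `p`, `df_between`, `df_within`, `tukey`
#'   (data.frame: pair, diff, p_adj) and `letters` (named character).
#' @export
oneway_anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    df <- data.frame(value = groups$value,
                     group = factor(groups$group))
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)),
                     levels = names(groups)))
  }
  sizes <- table(df$group)
  if (length(sizes) < 2) stop("at least 2 groups are required")
  if (any(sizes < 2)) {
    stop(sprintf("group(s) with < 2 replicates: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk),
                      diff = unname(tk[, "diff"]),
                      p_adj = unname(tk[, "p adj"]),
                      stringsAsFactors = FALSE)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = 1 - alpha)$mcletters$Letters
  list(F = unname(an[1, "F value"]), p = unname(an[1, "Pr(>F)"]),
       df_between = unname(an[1, "Df"]), df_within = unname(an[2, "Df"]),
       tukey = tukey, letters = letters[levels(df$group)])
}
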