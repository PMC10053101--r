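#!/usr/bin/env Rscript
# Deglycosylation dose-response: fit the four-parameter logistic to the
# simulated PNGase-F dose table, and summarize the deglycosylation
# effects on maximal activity and affinity along the gut axis using the
# published kinetic estimates as inputs to the comparison conventions.

suppressPackageStartupMessages(library(apkin))
dir.create("results", showWarnings = FALSE)

d <- read_assay_table("results/data/dose-response.csv", "dose_response")
f <- fit_sigmoid_dose_response(d)
cat(sprintf(
  "Sigmoid fit: Bo = %.2f +/- %.2f, To = %.2f +/- %.2f, ED50 = %.0f +/- %.0f U/mg, hill = %.4g, R2 = %.3f\n",
  f$Bo, f$se_Bo, f$To, f$se_To, f$ED50, f$se_ED50, f$hill, f$r_squared))
cat(sprintf(
  "The residual activity falls from the %.2f plateau to %.2f; half the loss is reached near %.0f U/mg,\nso the 7150 U/mg working dose sits on the lower plateau (complete deglycosylation).\n",
  f$To, f$Bo, f$ED50))
utils::write.csv(
  data.frame(parameter = c("Bo", "To", "ED50", "hill"),
             estimate = c(f$Bo, f$To, f$ED50, f$hill),
             se = c(f$se_Bo, f$se_To, f$se_ED50, f$se_hill),
             r_squared = f$r_squared, n = f$n),
  "results/dose_response_fit.csv", row.names = FALSE)

# published per-segment kinetic estimates (untreated vs deglycosylated)
seg <- data.frame(
  segment = c("jejunum", "ileum", "cecum", "colon"),
  Vmax_untreated = c(27.74, 21.26, 3.08, 10.00),
  Vmax_pngase = c(12.05, 11.73, 3.99, 11.04),
  Km_untreated = c(25.47, 24.67, 22.08, 39.50),
  Km_pngase = c(29.21, 20.59, 182.30, 59.51))
seg$Vmax_reduction_pct <- round_half_away(
  percent_change(seg$Vmax_untreated, seg$Vmax_pngase, "reduction"))
seg$Km_increase_pct <- round_half_away(
  percent_change(seg$Km_untreated, seg$Km_pngase, "increase"))
utils::write.csv(seg, "results/deglycosylation_effects.csv",
                 row.names = FALSE)

cat("\nDeglycosylation effects (printed kinetic estimates as inputs):\n")
for (i in seq_len(nrow(seg))) {
  cat(sprintf("  %-8s Vmax change %+4d%%, Km change %+4d%%\n",
              seg$segment[i], -seg$Vmax_reduction_pct[i],
              seg$Km_increase_pct[i]))
}
cat("Small-intestinal segments lose maximal activity; large-intestinal\nsegments lose affinity (Km rises) instead.\n")
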