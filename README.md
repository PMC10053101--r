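# apkin

Quantitative analysis of gut alkaline phosphatase (AP) isoform kinetics
and the effect of glycosylation on them.

Intestinal alkaline phosphatases are apical-membrane glycoenzymes that
dephosphorylate endotoxin and other pathogen-associated molecules; their
functionality is summarized by the Michaelis constant *K*m (inverse
substrate affinity) and the maximal specific activity *V*max. This
package implements, as tested reusable functions, the complete analysis
chain used to characterize how N-glycosylation shapes those parameters
in the weaned porcine gut and in a recombinant *E. coli* expression
system:

* **Assay layer** — conversion of p-nitrophenol absorbance changes and
  time-course slopes into specific activities (1 U = 1 nmol/min per mg
  protein).
* **Model fitting** — unweighted nonlinear least squares for
  Michaelis–Menten kinetics `v = Vmax·S/(Km+S)`, the four-parameter
  logistic dose-response
  `Y = Bo + (To−Bo)/(1 + 10^((ED50−x)·h))` used for enzymatic
  deglycosylation (PNGase-F) titrations, and exponential
  `Y = J0·e^(b·x)` / quadratic thermal-response models.
* **Thermal-inhibition estimation** — an Eadie–Hofstee-style
  linearization regressing residual activity *J* on *J/I* (temperature
  *I*, °C) to report `TC50` (slope magnitude), `I_MIN` (intercept),
  `I_MAX = I_C − I_MIN` and the control activity `I_C`, with
  significance gating: when the slope's p-value exceeds 0.05 the
  parameters are reported as `NS`, never silently dropped.
* **Partitioning** — isoform-specific kinetics from lysate mixtures,
  either point-wise (total − background activity per substrate level,
  then refit) or as a parameter difference with quadrature SE.
* **Inhibitor fractionation** — normalization of L-phenylalanine
  (IAP-selective) and L-homoarginine (TNAP-selective) inhibition tables
  to the 0-mM baseline and classification of isoform dominance per gut
  segment.
* **Comparisons** — the excess-over-baseline fold convention
  `(max−min)/min`, percent-change arithmetic, pooled two-tailed t-tests
  on parameter estimates, and one-way ANOVA with Tukey HSD and compact
  letter displays.
* **Sequence accounting** — N-glycosylation sequon scanning
  (N-X(≠P)-[S/T], 1-based positions on the untrimmed chain) and
  average-mass computation of optionally signal-/GPI-trimmed chains.
* **Synthetic data** — seeded, bit-reproducible generators for every
  design above, so the whole pipeline runs and is tested without any
  laboratory data.

## Worked example

Simulate a 16-level substrate gradient for a vector-only *E. coli*
lysate, fit it, and partition the recombinant-isoform-specific maximal
activity:

```r
library(apkin)

fit_total     <- fit_michaelis_menten(gen_kinetic(preset("table4-total",     seed = 1)))
fit_intrinsic <- fit_michaelis_menten(gen_kinetic(preset("table4-intrinsic", seed = 1)))
fit_intrinsic
#> <mm_fit> Km = 4283 +/- 482 uM, Vmax = 0.9311 +/- 0.0554, R^2 = 0.9761 (n = 64)

partition_parameters(fit_total, fit_intrinsic)$Vmax
#> [1] 0.773795
```

With the noise switched off the generators close the loop exactly
(`preset("table4-intrinsic", noise_sd = 0)` refits to Km = 4068.0,
Vmax = 0.89 to machine precision), and with the published estimates as
direct inputs the parameter-difference partition is exact:

```r
partition_parameters(list(Vmax = 1.64, se_Vmax = 0.07, converged = TRUE),
                     list(Vmax = 0.89, se_Vmax = 0.05, converged = TRUE))$Vmax
#> [1] 0.75
```

The numbered scripts under `analysis/` run the full study flow
(simulate → fraction kinetics → inhibitor fractionation →
deglycosylation dose-response → partition and thermostability → sequon
accounting) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_datasets.R
Rscript analysis/02_fraction_kinetics.R
# ...
Rscript analysis/06_sequon_mass_accounting.R
```

For example, `analysis/03_inhibition_fractionation.R` prints the
per-segment isoform calls:

```
jejunum  L-Phe inhibition  76.9%, L-hArg  24.2% at 100 mM -> IAP-dominant
ileum    L-Phe inhibition  90.1%, L-hArg  13.3% at 100 mM -> IAP-dominant
cecum    L-Phe inhibition  31.5%, L-hArg  39.9% at 100 mM -> mixed
colon    L-Phe inhibition  25.7%, L-hArg  29.6% at 100 mM -> mixed
```

meaning the small-intestinal segments lose most of their activity to
the IAP-selective inhibitor alone, while both isoform families
contribute in the large intestine.

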