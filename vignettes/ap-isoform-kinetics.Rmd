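---
title: "Models and methods for gut alkaline phosphatase isoform kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for gut alkaline phosphatase isoform kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apkin)
```

## The scientific problem

Gut alkaline phosphatases (AP) are GPI-anchored apical-membrane
glycoenzymes that dephosphorylate endotoxin lipopolysaccharide and other
pathogen-associated molecules, so their catalytic capacity and affinity
bear directly on gut homeostasis. Two isoform families matter here: the
intestinal-type isoforms (IAP, selectively inhibited by
L-phenylalanine) and the tissue-nonspecific isoforms (TNAP, selectively
inhibited by L-homoarginine). Enzyme functionality is summarized by the
Michaelis constant $K_m$ (µM; larger means lower substrate affinity) and
the maximal specific activity $V_{max}$ (nmol product per mg protein per
minute). `apkin` packages the full analysis chain used to ask how
N-glycosylation modulates these parameters: purified-glycoform kinetics,
enzymatic deglycosylation dose-response, isoform-specific partitioning
from recombinant lysates, thermal inhibition, and the sequence-level
sequon/mass bookkeeping behind the glycoform interpretation.

## Units and data model

Substrate concentrations are stored internally in µM; tables supplied in
mM are multiplied by 1000 on ingestion and the normalization is
idempotent. Activities are specific activities, 1 U = 1 nmol/min per mg
protein. Percent-of-control series carry an explicit `is_relative` flag
rather than being guessed from magnitudes. Every fitted stage returns
parameters with standard errors, or an explicit `"NS"` marker — a
parameter is never silently absent. Results serialize to key-sorted
full-precision JSON so identical analyses produce byte-identical files.

## Models

**Michaelis–Menten.** $v = V_{max} S / (K_m + S)$, fitted by unweighted
Levenberg–Marquardt least squares (no weighting scheme is assumed for
the replicate structure). Starting values are $V_{max,0} = \max v$ and
$K_{m,0}$ = the lowest substrate level whose mean velocity exceeds
$V_{max,0}/2$. Convergence tolerance is $10^{-10}$ on the residual sum,
at most 200 iterations and 5 jittered restarts. $R^2$ for all nonlinear
fits is $1 - SS_{res}/SS_{tot}$ about the response mean. Both entry
modes — all replicates, or per-level replicate means — are supported,
because published designs mix them; the mode used is recorded with the
fit.

**Dose-response (four-parameter logistic).**
$Y = B_o + (T_o - B_o) / (1 + 10^{(ED_{50} - x)\,h})$, with $B_o$/$T_o$
the plateau activities, $ED_{50}$ the half-effect dose (U PNGase-F per
mg protein) and $h$ the steepness, whose sign sets the direction — the
response direction is data-driven, not constrained. A printed form of
this model with the dose axis rescaled by 1/500 and the steepness
absorbed into that rescaling corresponds to the canonical
parameterization $B_o = 1.98$, $T_o = 4.95$, $ED_{50} = 4605$,
$h = -0.002$, which is what the `fig5` preset generates. Starting
values: plateaus from the observed extremes, $ED_{50}$ from the dose
nearest mid-response, and $h_0 = \pm 2/\mathrm{range}(x)$ — a
slope-scale start; a unit-magnitude start overflows $10^{x}$ on dose
axes spanning thousands of units. Because few doses fall in the
transition region, a single start can hit a singular gradient, so the
fitter walks a small grid of $ED_{50}$ and steepness starts and keeps
the first converged fit.

**Thermal responses.** The exponential model $Y = J_0 e^{b x}$
(log-space initialization when all responses are positive; an exactly
constant series returns $J_0 = \bar Y$, $b = 0$) and the quadratic
$Y = c_0 + c_1 x + c_2 x^2$ by ordinary least squares. The sign of $b$
is unconstrained: intrinsic bacterial AP activity *rises* with
treatment temperature while the recombinant porcine isoform decays.

**Thermal inhibition (Eadie–Hofstee-style linearization).** Residual
activity $J$ after a 30-min treatment at temperature $I$ (°C) is
regressed on $J/I$:

$$J = I_{MIN} + \beta\,(J/I), \qquad TC_{50} = |\beta|, \qquad
  I_{MAX} = I_C - I_{MIN},$$

where $I_C$ is the control-group (lowest temperature, 22 °C) mean
activity. The linearization is conventionally written with a negative
slope, but the empirical fitted lines have positive slopes and the
half-inhibition temperature is reported as that slope magnitude; the
raw signed slope is kept in diagnostics. Gating: if the slope's OLS
p-value exceeds 0.05, $TC_{50}$, $I_{MIN}$ and $I_{MAX}$ are reported as
`NS` and only $I_C$ is kept. An intercept that is itself not
distinguishable from zero (p > 0.05) is *reported* as 0 while the raw
estimate is preserved and still used in $I_{MAX} = I_C - I_{MIN}$, which
keeps that identity exact — using the reported zero instead would not
reproduce the published $I_{MAX}$ values. The control point is included
in the regression, which matches the published sample sizes (6
temperature levels × 4 replicates = 24). $TC_{50}$ is exactly invariant
to rescaling the activities to percent of control, since both axes of
the regression scale together.

## Partitioning and fractionation

Isoform-specific kinetics are partitioned from lysate mixtures two
ways, and the method is always labeled:

* **parameter difference** — $V_{max}^{specific} = V_{max}^{total} -
  V_{max}^{background}$ with quadrature SE
  $\sqrt{se_1^2 + se_2^2}$ (a Monte-Carlo resampling oracle confirms
  quadrature to within 2%);
* **point-wise** — per-substrate-level difference of replicate means,
  then a Michaelis–Menten refit. The difference of two hyperbolas is
  not itself a hyperbola, so the refit is an approximation; on
  noise-free curves built from the published total and background
  parameters the best least-squares $K_m$ of the difference (by
  exhaustive grid search) is ≈ 2420 µM, and the grid-search oracle —
  not any published number — is what the tests hold the fitter to.
  Negative differences are retained with a warning; clipping them would
  bias the refit.

Inhibition tables are normalized to the 0-mM baseline (taken as 100%
residual activity; `inhibited = 100 − residual` holds in every row by
construction), and a segment is classified IAP-dominant when L-Phe
inhibition at the top concentration (default 100 mM) reaches the
threshold (default 50%) while L-hArg inhibition stays below it;
TNAP-dominant in the mirror case; mixed otherwise. The threshold is
configurable because the underlying classification is narrative, not a
published cutoff.

## Comparison conventions

Fold differences use the excess-over-baseline convention
$(\max-\min)/\min$ — the only convention that reproduces the published
6.4-fold (mature vs pre-mature fraction affinity) and 6.5-fold
(recombinant vs pre-mature affinity) claims from the corresponding
table values — with the direction reported separately and the plain
ratio available but never default. Percent changes are
$100(\mathrm{new}/\mathrm{ref}-1)$ for increases and
$100(\mathrm{ref}-\mathrm{new})/\mathrm{ref}$ for reductions; reported
percentages round half-away-from-zero to integers, matching prose
style. Parameter estimates are compared by the pooled two-tailed
t-test $t = (a-b)/\sqrt{se_a^2+se_b^2}$ with the conservative
$df = \min(df_a, df_b)$, where each fit contributes
$df = n - (\text{number of fitted parameters})$ — published tables
print $n$ (30, 64) but never df, so the conservative choice is the
package's own. Group endpoints use one-way ANOVA with Tukey HSD and a
compact letter display mirroring table superscripts.

## Sequence accounting

Sequon scanning applies the canonical rule N-X(≠P)-[S/T]; overlapping
sequons are all reported and no veto is applied at the third position.
Positions are 1-based on the untrimmed chain so they are directly
comparable to "N141"-style annotations. Chain masses use pinned
*average* (not monoisotopic) residue masses with one water for the
terminal groups; trimming removes the signal peptide
(`signal_end + 1 .. end`) or both signal and GPI-anchor region
(`signal_end + 1 .. gpi_omega`). The ω-site is a user input: published
"C-30"-style annotations are ambiguous between an ω-residue index and a
C-terminal propeptide length, so no convention is imposed. Neural
glycosylation-site scoring and signal-peptide/GPI prediction are out of
scope; their outputs enter only as numeric boundaries.

## The synthetic-data generators

Every design in the analysis has a seeded, bit-reproducible generator
with additive Gaussian noise on the response scale (the emulated
designs report symmetric ± SE throughout; heteroscedastic noise is
deferred). The default grids are the two published substrate-gradient
designs — 10 levels over 0–0.8 mM and 16 levels over 0–6 mM — realized
with approximately geometric spacing so each design brackets the
half-saturation point of its target kinetics (the published designs
state ranges and level counts but not spacings), the six-dose PNGase-F
titration `0, 1430, 4289, 7150, 8579, 12868` U/mg, and a 22–80 °C
thermal grid of 6 levels × 4 replicates (n = 24, matching the published
thermostability sample size; the level positions within the range are a
package choice). Preset `noise_sd` values are fixed calibrations chosen
so the simulated parameter SEs are of the same order as the published
SEs under each design (e.g. the 16-level intrinsic-lysate preset yields
$K_m$ SE ≈ 530 vs the published 525; the partitioned preset ≈ 450 vs
450.8), and were set once from that criterion.

The thermal-inhibition forward model is a package construction (the
linearization itself has no usable forward form):
$J = I_C - I_{MAX}\, I'/(TC_{50} + I')$ with $I' = I - 22$, which is
exactly linear on the *inhibition* scale — regressing
$D = I_C - J$ on $D/I'$ recovers $I_{MAX}$ and $TC_{50}$ to machine
precision, and the tests use that as the oracle that the generator
implements its stated model.

The two-isoform mixture generator assumes strict inhibitor
specificity: under L-Phe the group mean is
$\mathrm{total}\,[f_{IAP}(1-\varphi_{Phe}(c)) + f_{TNAP}]$ and
mirrored for L-hArg. Under this assumption the maximal inhibitions by
the two inhibitors cannot sum past 100%, so published per-segment
percentages that do (e.g. cecal 55% + 54%) cannot be reproduced
exactly; the presets reproduce the qualitative dominance patterns
instead, which is what the classification consumes.

## What the tests do and do not show

Noise-free generate-then-fit loops recover every preset's generating
parameters to relative error < 10⁻⁶, and the OLS-based estimators agree
with closed-form normal-equations oracles to machine precision. Under
calibrated noise, 200-seed recovery runs hold the generating parameters
inside estimate ± 3 SE in ≥ 90% of runs for the Michaelis–Menten
parameters and for the dose-response plateaus and $ED_{50}$. The
dose-response *steepness* is excluded from that criterion: with only
one dose in the transition region its Wald interval is unreliable (its
coverage stays near 65% at any noise level — a standard four-parameter
logistic caveat), which is consistent with the emulated study reporting
no independent steepness SE. Because the generators use additive
Gaussian noise on an exactly correct model family, passing these tests
demonstrates the estimators, not the realism of any laboratory error
structure — pipetting error, heteroscedastic plate noise and
between-animal variance components are all outside the generators'
scope.

## Known limitations

* The $J$-on-$J/I$ thermal linearization reproduces published fitted
  lines and tables, but its slope only *attenuatedly* tracks the
  half-inhibition temperature of the saturating forward model: on
  noise-free generated curves the slope underestimates the generating
  $TC_{50}$ substantially (estimates cluster well below generating
  values across realistic parameter ranges). The linearization is kept
  because it is the published procedure and its internal contracts
  (exact line recovery, NS gating, the $I_{MAX}$ identity, scale
  invariance) all hold; treating its slope as a physical half-inhibition
  temperature deserves caution.
* The implied forward curve of the positive-slope linearization,
  $J = I_{MIN}\,I/(I - TC_{50})$, is singular at $I = TC_{50}$; claims
  extrapolated from $2 \times TC_{50}$ have no derivation here and are
  not mechanized.
* The pooled t-test on parameter estimates treats the two estimates as
  independent Gaussians with known SEs; for partitioned parameters the
  quadrature SE (≈ 0.086 for the lysate $V_{max}$ pair) is what
  propagation gives, and smaller published SEs for partitioned
  quantities cannot be reproduced from the printed inputs.
* No substrate-inhibition, Hill-kinetic or multi-site models; no more
  than two isoform classes in mixtures; no mechanistic $K_i$ modelling
  of the inhibitors; no O-glycosylation prediction.
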