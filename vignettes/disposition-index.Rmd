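---
title: "Metabolic indices, the disposition-index hyperbola, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic indices, the disposition-index hyperbola, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycurve)
library(dplyr)
```

glycurve analyses studies in which the same subjects undergo a fasting blood
draw, a euglycemic-hyperinsulinemic clamp, and a liquid mixed-meal tolerance
test (LMMTT) sampled at 0, 30, 60, 90, 120 and 240 min. This vignette is the
package's account of the science: the model behind each computation, the
parameters that matter, what the synthetic-cohort generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## The index panel

All formulas operate on canonical units — glucose in mmol/l, insulin in
mU/l — and unit conversion happens only at the I/O boundary
(`convert_glucose()`, `convert_insulin()`; factors fixed at 18.0 mg/dl per
mmol/l and 6.0 pmol/l per mU/l, the first chosen so the clinical equivalence
90 mg/dl = 5 mmol/l is exact).

| index | formula | inputs |
|---|---|---|
| HOMA-IR | `FI * FG / 22.5` | fasting |
| HOMA-B | `20 * FI / (FG - 3.5)` | fasting |
| ISI-clamp | `(M / LBM) / I_ss * 100` | clamp steady state |
| ISI-Mat | `10000 / sqrt(FG * FI * IAUCg * IAUCi)` | fasting + meal |
| insulinogenic index | `(I30 - I0) / (G30 - G0)` | meal |
| secretion index | `AUC_ins / AUC_glu` | meal |
| oral DI | `ISI-Mat * secretion index` | derived |

Three of these needed decisions the defining formulas leave open:

**ISI-clamp scaling.** The raw ratio of glucose infusion rate per kg lean
mass to steady-state insulin is about 0.14 for a sensitive lean adult
(10 mg kg⁻¹ min⁻¹ at 70 mU/l), two orders of magnitude below the values on
which this index is conventionally reported (≈ 14). `isi_clamp()` therefore
defaults to `scale = 100`, records the scale on pipeline output, and accepts
`scale = 1` for the raw ratio. The schema takes the infusion rate as
absolute mg/min plus lean body mass and normalizes internally, so labs that
log either form can populate it.

**Matsuda-index grouping.** Composite sensitivity indices of this family
are printed ambiguously: the square root may cover only the fasting product
or the full four-term product. glycurve defaults to the root over the full
product (`grouping = "full"`), which matches the dimensional structure of
the original composite index (each factor enters with exponent −1/2); the
alternative reading is available as `grouping = "fasting_only"` and the
choice is recorded as an attribute on the panel. Note also that this
formulation uses *incremental* AUCs over the full test, which is not the
conventional mean-concentration form; the conventional variant is a
separately named function, `matsuda_isi_conventional()`, so the two can
never be conflated silently.

**Incremental-AUC convention.** The trapezoidal rule defines total AUC
unambiguously, but dips below the fasting baseline can either subtract
(net) or be clipped (positive-only, with exact linear interpolation of the
crossing points). glycurve defaults to net — the simpler reading, and the
one the composite index downstream consumes — and always reports both
conventions side by side in the panel (`iauc_*` and `iauc_*_pos`), with the
convention fed to ISI-Mat selectable via `iauc_convention`. No smoothing,
no extrapolation beyond the last sample: duration is exactly
`t_last − t_0`.

Degenerate inputs never abort a cohort: a fasting glucose at or below the
HOMA-B singularity (3.5 mmol/l), a zero 0–30 min glucose change in the
insulinogenic index, or a non-positive net incremental AUC each yield `NA`
for the affected index plus a human-readable entry in `exclusion_reason`.
There is no imputation anywhere, and index operations that need the 30-min
sample fail loudly rather than interpolate.

## The disposition-index hyperbola

Adequate beta-cell compensation means secretion `B` rises as sensitivity
`S` falls, with `S * B` constant: `B = k / S`. `fit_di_hyperbola()` fixes
the exponent at −1 (the model is asserted, not estimated — a free-exponent
power law answers a different question) and estimates only `k`:

* **log scale (default)**: least squares on `log B = log k − log S`, closed
  form `k = exp(mean(log(S_i B_i)))`, the geometric mean of the products.
  Physiological noise in these quantities is multiplicative, residuals on
  the log scale are symmetric, and the estimator is exactly equivariant
  under rescaling of either axis. Residuals have mean zero by construction.
* **linear scale**: `k = sum(B_i/S_i) / sum(1/S_i^2)`, the least-squares
  solution of `B = k/S`, retained because nonlinear regression on the raw
  scale is what plotting software typically fits; it down-weights low-`S`
  subjects less and is noticeably more sensitive to secretion outliers.

The per-subject compensation score is `r_i = log(S_i B_i) − log k`: zero on
the curve, negative below ("falling off the DI curve"). `place_groups()`
reports group means of coordinates and scores and ranks groups by mean
score. Two axis pairings are meaningful and both are supported: clamp
sensitivity against the meal-test secretion index (the default — the
sensitivity measure is then statistically independent of the meal test that
produced the secretion measure) or ISI-Mat against the secretion index
(fully meal-derived, as in the oral DI itself). The axes used are recorded
in the fit object.

## Group statistics

`compare_groups()` is classic ANCOVA: a linear model of the outcome on the
covariate plus group indicators, the F test of the group factor, adjusted
group means at the grand covariate mean, and pairwise contrasts of adjusted
means using the model covariance, Bonferroni-corrected over the number of
pairs (p-values capped at 1, always two-sided; the 0.05 threshold is a
report annotation, never a filter). A covariate with zero variance is
detected and dropped, making the reduction to one-way ANOVA exact rather
than an accident of rank-deficient fitting.

`rm_anova()` is the univariate split-plot decomposition for a between
factor (group) crossed with a within factor (time), by explicit sums of
squares. With unequal group sizes the weighted (cell-mean) decomposition is
used, under which both partitions are exact:
`SS_total = SS_between-subjects + SS_within` and
`SS_within = SS_time + SS_interaction + SS_error` (verified to 1e-8 in the
tests, and cross-checked against `aov(... + Error(subject))`). Two points
are under-specified in how such analyses are usually reported, so both
variants are emitted rather than chosen silently:

* **Sphericity.** The Greenhouse–Geisser epsilon is estimated from the
  pooled within-group covariance and the within-subject tests are reported
  uncorrected *and* with epsilon-scaled degrees of freedom.
* **Covariate adjustment.** "Adjusted for age" is ambiguous in a
  within-subject design. glycurve enters the covariate in the
  between-subject stratum only (ANCOVA on subject means) — the classic
  split-plot ANCOVA. A subject-constant covariate lies entirely in the
  between-subject stratum, so the time and interaction tests are
  algebraically identical with and without adjustment; the group test is
  reported both ways.

`compare_excursion()` feeds this machinery the incremental change from
baseline at the five post-baseline timepoints (the baseline row is
identically zero for every subject and carries no information). Pairwise
group contrasts at each timepoint use the pooled within-timepoint error
with Bonferroni over pairs only — matching how per-timepoint differences
are conventionally annotated on excursion figures — rather than over
pairs × timepoints; the full correction can be applied downstream since raw
p-values are reported.

`bootstrap_group_di()` supplies percentile bootstrap intervals for group DI
means (subject-level resampling within group, seed-reproducible).

## The synthetic cohort

No individual-level data ship with the package; the generator is the
test-bed, and its defaults encode the study conditions the package targets.
Per subject in group *g*:

1. true sensitivity `S_i` ~ lognormal with the group's mean and SD on the
   clamp-index scale;
2. true secretion `B_i = delta_g * k_g / S_i * exp(eps_i)`,
   `eps_i ~ N(0, sigma_log^2)` with `sigma_log = 0.25` — subjects scatter
   multiplicatively about the group hyperbola, shifted below it by the
   compensation deficit `delta_g ∈ (0, 1]`;
3. fasting insulin `FI_i = c_g / S_i * exp(nu_i)` (anti-correlated with
   sensitivity, as hyperinsulinemia compensates resistance), fasting
   glucose truncated-normal below the 7 mmol/l normoglycemic bound;
4. glucose curve `G(t) = FG_i + A_i h(t)` with a fixed unimodal kernel
   `h(t) = (t/45)^2 exp(2(1 − t/45))` — peak 1 at 45 min, `h(0) = 0`,
   `h(240) ≈ 0.005` — and amplitude `A_i ∝ 1/(S_i B_i)`: the lower the
   disposition index, the larger the glycemic excursion. A parametric
   kernel rather than an ODE minimal model keeps the ground truth
   interpretable, and nothing downstream uses curve mechanics beyond the
   sampled points;
5. insulin curve `I(t) = FI_i + B_i A_i h(t − 15)` (15-min lag);
6. clamp record with steady-state insulin ~ N(70, 8²) mU/l — a plausible
   level under the standard 40 mU m⁻² min⁻¹ infusion, recorded as a preset
   constant — and infusion rate `M_i = S_i I_ss LBM_i / 100`, so ISI-clamp
   reconstructs `S_i` exactly and all clamp-side recovery error is
   attributable to downstream estimators.

All bounds (positivity, fasting glucose < 7 mmol/l, lean BMI < 23, adult
age) are enforced by resampling, never clipping, preserving distribution
shape near the bounds. Byte-identical output under a fixed seed; the
caller's RNG state is saved and restored.

`cohort_presets()` freezes three groups of 14/21/24 subjects calibrated to
published group summaries of lean Asian men (clamp sensitivity means
14.2/12.9/8.8; fasting glucose 4.41/4.12/4.12 mmol/l; fasting insulin
4.85/5.93/7.54 mU/l; incremental glucose AUC targets 157.0/306.0/224.6
mmol·min/l). Between-subject SDs are reconstructed from printed standard
errors as SE·√n using the cohort group sizes (the summaries' header n is
inconsistent with the cohort; the cohort sizes are used throughout). The
first and third groups compensate appropriately (`delta = 1`, `k` = mean
sensitivity × mean secretion index: 149.1 and 108.2); the second shares the
first group's reference hyperbola with `delta ≈ 0.79`, reproducing the
below-the-curve pattern. The excursion-amplitude constant is frozen per
group from its incremental-AUC target (with lognormal mean corrections),
and lean body mass (52 ± 5 kg) is a realistic value for lean adult males
since the summaries do not print one. `null_preset()` gives three identical
groups for type-I-error studies.

**What the generator does not emulate.** Insulin excursion amplitudes are
tied to `B_i A_i` and come out compressed relative to typical assay values
(incremental insulin AUCs of order 2000–3000 rather than ~10000 mU·min/l);
consequently absolute ISI-Mat values run higher than published ones, while
every ordering and invariance property is preserved. The excursion shape is
a single kernel scaled per subject, so the within-subject covariance of the
post-meal deltas is essentially rank-one and the Greenhouse–Geisser epsilon
sits at its lower bound `1/(T−1)` — real curves have richer temporal
structure. There is no incretin axis, no C-peptide, no hepatic insulin
extraction, and no attempt to match lipid panels. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not fidelity of that model to any particular assay.

**Recovering the compensation deficit.** `recovery_report()` fits the
reference hyperbola to the `delta = 1` subjects' ground-truth coordinates
and scores every group against it, so a group generated with deficit
`delta` has expected mean score `log(delta)` exactly. Two design points
deserve emphasis. First, fitting the curve to *all* subjects forces the
mean residual to zero, which redistributes any deficit across groups; a
deficit is only identified relative to a reference population assumed to
compensate appropriately — in real data that assumption is a scientific
judgement, here it is part of the ground truth. Second, the recovery runs
on the generative `(S, B)` coordinates: the *measured* secretion index is
an AUC ratio whose numerator and denominator are dominated by the baseline
rectangles, and under the excursion coupling `A ∝ 1/(S·B)` the product
`B·A` is independent of `delta`, so the measured index attenuates the
deficit far below `log(delta)`. Group *rankings* by off-curve score are
unaffected by either issue and are verified on both ground-truth and
measured coordinates.

## Problem sizes and tolerances

The test suite runs the formula oracles on 1000 random inputs at 1e-10
relative tolerance; AUC against 0.001-min dense-grid integration of the
interpolant (1e-6); the hyperbola estimator against a refining grid search
(1e-6) and parameter recovery at n = 200 within 5%; deficit recovery at
n = 500 per group within 0.1 of `log(0.6)` plus correct ranking in ≥ 95 of
100 seeds at n = (14, 21, 24); ANCOVA null calibration over 1000 simulated
cohorts of 3 × 20 subjects (rejection rate within [0.035, 0.065] at
α = 0.05); the split-plot interaction against the squared two-sample t on
difference scores (1e-8); and the preset orderings (lowest clamp
sensitivity in the third group, highest glucose IAUC and lowest oral DI in
the second) in ≥ 90 of 100 seeds. The full suite completes in about a
minute on one CPU.

```{r example}
cohort <- simulate_cohort(cohort_presets(), seed = 42)
panel <- compute_indices(cohort)
place_groups(panel)
```
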