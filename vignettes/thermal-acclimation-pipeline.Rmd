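---
title: "Methods: thermal acclimation pipeline for lake trout respirometry and CTmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal acclimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement models, the inference layer, the synthetic-data generator
that stands in for the unpublished raw data, and the design choices made
where the underlying protocol left the details open.

## The experimental system

Juvenile lake trout from four hatchery-held populations (Myrt Lake, Lake
Louisa, Opeongo Lake, Lake Manitou), reared in a common garden from
fertilisation, are acclimated to 8, 11, 15 or 19 °C and assessed for
upper thermal tolerance (critical thermal maximum, CTmax) and aerobic
metabolism (routine and maximal metabolic rate, metabolic scope, and
recovery from exhaustive exercise). The inferential question is a
factorial one: does acclimation temperature shift each trait, do
populations differ, and — the acclimation-capacity question — is there a
population × temperature interaction?

## Respirometry reduction

**Closed-phase slopes.** During a closed phase the chamber oxygen
concentration declines linearly; `fit_o2_slope()` fits ordinary least
squares of O2 (mg l⁻¹) on time (min). No samples are trimmed by default
(`trim_start = 0`): the traces are modelled without a mixing transient,
and trimming is exposed for real data that have one. A rising trace
yields a negative decline; it is *retained* and QC-flagged rather than
clamped, so the inference layer sees unbiased values rather than a
truncated distribution.

**Whole-animal MO2.** Slopes convert to oxygen consumption as
`MO2 = (decline − blank) × (V − Vm) × 60` with `V` the chamber volume
(1.1 l by default) and `Vm` the fish volume. Fish volume is computed as
`mass (g) / 1000 / density` litres with tissue density 1.0 g ml⁻¹
(configurable); background (bacterial) respiration is estimated as the
mean fitted decline of fishless blank runs and subtracted on the
concentration-rate scale before the volume multiplication. The pipeline
pools all blanks into a single rate; a per-chamber rate can be passed
explicitly to `process_respirometry()`.

**RMR.** The mean of the three closed-phase MO2 values; a different
count is flagged (`count_flag`) but tolerated.

**MMR by back-extrapolation.** After a chase to exhaustion
(~4.75 min) and a ~10–15 s transfer, oxygen consumption is measured in
eight 5-min windows alternating with 5-min flushes, spanning exactly
75 min. `fit_recovery_curve()` regresses MO2 on `ln t`, with `t` the
window midpoint in minutes since chamber re-entry (midpoints 2.5, 12.5,
…, 72.5). Two conventions needed fixing:

* *The "intercept" of a logarithmic curve.* `a + b·ln t` diverges at
  `t = 0`, so the back-extrapolated MMR is defined as the fitted value at
  `eval_time = 1` min, where `ln t = 0` — i.e. exactly the regression
  intercept, representing the rate "immediately after exhaustion".
  `eval_time` is configurable (e.g. 0.25 min to extrapolate to the
  transfer time) and is recorded in the fit object; whether the original
  analysis evaluated at 1 min or at transfer time is not determinable, so
  both are exposed and neither is asserted as exact historical practice.
* *Logarithm base.* Natural log is used. The base only rescales the
  slope `b1`; the default MMR (the value at `t = 1`) is base-invariant.

The highest observed post-chase value (`mmr_peak()`, earliest window on
ties) is carried alongside as the non-extrapolated alternative.
Metabolic scope is `MMR − RMR` per fish (flagged, not rejected, if
non-positive), and `b1` is the recovery-rate statistic.

## Thermal tolerance

Ramps are treated as exactly linear: `T(t) = start + rate·t` with the
default rate 0.17 °C min⁻¹ and the start at the group's acclimation
temperature. `ctm_values()` accepts loss-of-equilibrium events stored
either as elapsed times (mapped through the ramp) or as recorded
temperatures (passed through), and the two storages are
interchangeable to within 1e−9 °C. CTmax is reported per fish; trial- or
tank-level aggregation is deliberately left to the inference layer so
tanks never silently become the unit of analysis.

## Inference layer

All factorial fits are ordinary linear models. Metabolic rates, body
mass and condition factor are log10-transformed (variance
stabilisation); CTmax, fork length and the (negative) recovery slope are
analysed on the raw scale.

* **ANOVA/ANCOVA.** `two_way_anova()` fits `A * B`;
  `two_way_ancova()` fits `covariate + A + B + A:B` with the covariate
  first. Sums of squares are sequential (Type I) — the default behaviour
  of `anova()` in the statistical environment this analysis tradition
  uses — with population before acclimation temperature; a Type III
  option (sum-to-zero contrasts via `car::Anova`) is provided and is
  near-identical for this nearly balanced design.
* **Mass exponents.** With both response and covariate on log10 scale,
  the ANCOVA common slope *is* the allometric mass exponent. This is the
  default estimator (`mass_exponent(..., method = "ancova")`); the pooled
  simple regression is available since either could underlie a published
  exponent.
* **Adjusted means.** `adjusted_means()` predicts group means at a
  reference mass (default 108.6 g, a study-wide mean body mass) via
  `emmeans`, averaging over the other factor with equal weights;
  back-transformed means with delta-method SEMs are the default
  reporting scale for transformed responses. Means are invariant to
  recentring the covariate, and a reference outside the observed mass
  range warns.
* **Homogeneity of slopes.** An extra-sum-of-squares F-test of all
  covariate × factor terms added to the common-slope model; the ANCOVA
  assumption check.
* **Tukey HSD.** All pairwise comparisons within a factor using the
  studentized range on the model residual df (Tukey–Kramer under
  imbalance), applied only after a significant omnibus F at α = 0.05.
  With two groups it reduces exactly to the pooled-variance t-test.
* **Condition factor.** Fulton's `K = 100·M/L³` (M in g, L in cm). This
  formula reproduces the respirometry-cohort reference values
  (e.g. 116.9 g, 20.7 cm → 1.3) to the printed precision; some published
  thermal-trial cell means are not consistent with any cubic condition
  index and are not modelled further.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are not tuning
knobs. Per design cell it draws body masses lognormally around the
published cell means (CV 0.12, inferred from printed SEMs at n ≈ 10) and
inverts Fulton's K (`L = (100·M/K)^(1/3)`, 2% length noise) so generated
cells hit the published condition-factor targets. The respirometry
design realises 158 of 160 planned fish (two cells of 9); the CTmax
design is a full 10 per cell.

Latent physiology:

* whole-animal `RMR = rmr_ref(temp) · (M/108.6)^1.12 · ε` and
  `MMR = mmr_ref(temp) · pop · (M/108.6)^0.82 · ε`, with lognormal
  between-fish scatter ε (CV 0.10) and a 6% MMR uplift for Lake Manitou
  (the one population effect the study supports). Published whole-animal
  anchors pin `rmr_ref` at 8 °C (5.26 mg O2 h⁻¹ ≡ 48.41 mg O2 kg⁻¹ h⁻¹
  at 108.6 g) and 19 °C (13.4), and `mmr_ref` at 8 and 15 °C; the 11 °C
  values are interpolated to respect the reported ~3-fold RMR rise and
  20–30% MMR rise to its 15 °C peak followed by a decline at 19 °C.
  Scope allometry is *emergent* (scope = MMR − RMR per fish), because
  three exponents (1.12, 0.82, 0.71) cannot all be imposed
  simultaneously; the scope exponent is recovered only approximately.
* recovery truth `MO2(t) = MMR + b1·ln t` with `b1` per acclimation
  temperature (−5.5, −6.0, −6.5, −4.0 mg O2 h⁻¹ per ln-min; slower
  recovery at 19 °C, Lake Manitou 0.5 steeper), floored at the fish's
  RMR so late recovery cannot undershoot rest, plus 5% CV window noise.
  The floor binds mainly for heavy 19 °C fish, which reproduces the
  reported significant mass covariate on recovery rate.
* CTmax drawn Normal(mean(temp), 0.5 °C) with means 26.1, 26.6, 28.1,
  28.9 °C — the published 8 and 19 °C bands, with the 11 and 15 °C
  means placed so the 11→15 °C step is ≈ 1.5 °C; population offsets are
  zero (no population effect was found). Draws at or below the ramp
  start are resampled (bounded retries).
* traces get Gaussian reading noise (SD 0.005 mg l⁻¹, 5 s cadence) on a
  9.5 mg l⁻¹ starting concentration plus a bacterial background slope of
  0.002 mg l⁻¹ min⁻¹ (~2% of a routine fish signal).

Between-fish SDs (metabolic CV 0.10, CTmax SD 0.5 °C, noise levels) are
*inferred*, not published — the study prints only SEMs of adjusted
means — and were chosen once as values a fish physiologist would call
realistic for juvenile salmonids. What the generator does **not**
emulate: probe drift, flush-phase mixing dynamics, tank hydraulics,
growth over the trial period, family structure within populations, or
any tank random effect. Passing tests therefore validate the reduction
and inference machinery on data with the assumed structure; they cannot
certify behaviour on real traces with transients or autocorrelated noise.

```{r}
library(troutherm)
cfg <- generator_config()
run <- run_pipeline(cfg, seed = 1, out_dir = "results/run")
```

## Numerical choices and degenerate inputs

* Slope and curve fits require ≥ 3 points, strictly increasing times and
  positive midpoints; violations raise classed data errors.
* `mmr_peak()` ties break to the earliest window.
* Empty design cells, single-level factors and insufficient residual df
  raise design errors naming the offending cell; a constant covariate is
  a rank error.
* All generators are bit-reproducible given a seed, and a pipeline run
  writes the seed plus an MD5 config hash into every output file.
* Validation problem sizes: oracle-equivalence checks run on single
  traces and small balanced toys; calibration and pattern-recovery
  checks use the full 158/160-fish design over 20 simulated replicates,
  and the homogeneity-of-slopes type-I calibration uses 200 replicates
  on the latent (trace-free) rates — sizes chosen to make Monte-Carlo
  error small relative to the effects being checked.

## Known limitations

* The "y-intercept" convention for back-extrapolated MMR is a modelling
  decision (value at 1 min), not a documented historical fact.
* Whether published mass exponents came from the ANCOVA common slope or
  a pooled regression is unknown; both are provided.
* Condition-factor cell targets genuinely differ between cells, so
  simulated K can show a population × temperature interaction that the
  original analysis did not detect; no acceptance check depends on it.
* No mixed models: the replicate-tank random effect noted as a
  robustness analysis in the source tradition is out of scope, as are
  EPOC integration, quantile-based SMR estimators and thermal
  performance curves.
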