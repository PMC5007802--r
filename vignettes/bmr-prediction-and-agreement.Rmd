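---
title: "Measuring, predicting and validating basal metabolic rate with bmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring, predicting and validating basal metabolic rate with bmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmrkit)
```

## The problem

Basal metabolic rate (BMR) is the minimal waking energy expenditure of a
fasted, rested adult under thermoneutral conditions, and it is the anchor
for estimating daily energy requirements (total expenditure is commonly
expressed as BMR multiplied by a physical activity level). The reference
measurement is indirect calorimetry — inferring energy expenditure from
oxygen consumption and carbon dioxide production — but calorimetry is not
feasible in routine practice, so anthropometric prediction equations are
used instead. Because the classical equations were developed largely in
Caucasian, normal-weight cohorts, they overestimate BMR in Asian and in
overweight populations, which motivated a weight-and-gender equation
calibrated on Singaporean Chinese adults across a wide BMI range.

`bmrkit` implements that full workflow: gas-exchange processing into a
measured BMR, a registry of published prediction equations, stepwise
derivation of new equations, the agreement/accuracy validation battery,
and a synthetic cohort generator that reproduces the calibration study's
statistical structure so every step is testable without subject-level
data.

## From gas exchange to measured BMR

A ventilated-hood session yields VO2 and VCO2 (L/min, STPD) every 5 s for
30 min. Processing has three stages.

**Habituation discard.** Subjects take several minutes to settle under the
hood, so the first `discard = 300` s are dropped.

**Steady-state selection.** Only quiet stretches of the recording should
contribute. A window of `window = 600` s slides over the post-discard
series in steps of one sampling interval; within each window the
coefficient of variation (CV = SD/mean) of each gas is computed. Windows
qualify when both CVs are at or below `cv_max = 0.10`; among qualifying
windows the one minimising `cv_vo2 + cv_vco2` wins, with ties broken by
earliest start. The protocol literature states the 10-min steady-state
requirement but no numeric variability rule, so the CV ≤ 10% criterion —
a common metabolic-cart convention — is adopted here; all three constants
are arguments. The argmin-plus-earliest-tie rule makes selection
deterministic, and a failed search raises a structured error
(`bmrkit_no_steady_state`) carrying the best window found, so a caller can
distinguish "no steady state" from other failures and report the CVs that
were achieved.

**Weir conversion.** Window means of VO2 and VCO2 are converted with the
abbreviated Weir formula,

$$\mathrm{EE} \;(\mathrm{kJ/d}) = (3.941\,\dot V_{O_2} + 1.106\,\dot V_{CO_2})
\times 1440 \times 4.184,$$

i.e. kcal/min scaled to kJ/d. The urinary-nitrogen (protein) correction is
omitted deliberately: hood protocols do not collect urine, and the
correction changes adult resting values by about 1–2%. The constants are
exposed only through `weir_bmr()` so the conversion has a single home.

Windows are half-open `[start, start + window)` with the first sample at
t = 0; a 30-min series at 5 s therefore has 360 samples and 300 remain
after the 5-min discard.

A `series_to_bmr(all_windows = TRUE)` variant averages the Weir value over
every qualifying window rather than only the best one. The single-window
behaviour is the default because the protocol reports one steady-state
value per session; the averaging variant exists because "steady-state
periods" is sometimes read in the plural, and the choice is left explicit
rather than baked in.

## The prediction-equation registry

`builtin_equations()` returns the seven equations of the comparison study
— Singapore, Harris-Benedict (HB), Henry, Liu, Yang, Mifflin and Owen —
as sex-stratified, age-banded linear forms in weight W (kg), height H
(cm) and age A (years), all in kJ/d and at published precision (no
re-rounding at evaluation). Gender enters through per-sex intercepts; the
indicator convention everywhere is men = 1, women = 0. The Singapore
equation is

$$\mathrm{BMR} = 52.6\,W + 828\,G + 1960,$$

equivalently men: 52.6 W + 2788, women: 52.6 W + 1960.

Henry is the only age-banded registry member (18–30, 30–60, 60–70 per
sex). Band boundaries are half-open `[min, max)` with the oldest band
closed above, so age exactly 30 dispatches to the middle band and age 70
is still covered; published sources do not state the boundary handling,
and this rule gives deterministic dispatch. Ages outside all bands raise
an error naming the equation and age; an `extrapolate = TRUE` flag
(default off) instead reuses the nearest band's coefficients.
Single-band "Adult" equations cover 18–120 y.

One wrinkle in the source material deserves a note: the running text of
the derivation prints the new equation with a trailing "+ 468.36" that
neither the summary tables nor the abstract carry, and that is
inconsistent with the equation's own predicted means. The registry
implements the tabulated form; the stray constant is treated as a
typographical artifact.

BMI is weight/(height/100)² and is classified with the Asian cut-offs:
overweight above 23.0 kg/m², obese above 27.5, both boundaries counted in
the lower category. The accuracy tables use the two-way split at 23.0
(`bmi_stratum()`), again with 23.0 itself in the lower stratum, matching
the tables' "≤23 / >23" headers.

## Deriving an equation

`stepwise_derive()` reproduces the derivation procedure: ordinary least
squares with forward selection over weight, height, age and gender.
At each step, every remaining candidate is test-added; candidates whose
partial-F p-value is below `entry_p = 0.05` qualify, and among qualifying
candidates the one giving the largest reduction in residual standard
deviation (RD) is added. Selection stops when nothing qualifies.
Equal-RD ties are broken alphabetically, purely for determinism. The
published account says only "stepwise"; forward selection is implemented
as the default because the reported trace (weight enters, then gender,
then nothing) is forward-shaped, and a bidirectional variant
(`direction = "both"`, removal at partial-F p > `remove_p = 0.10`) is
available behind a flag.

Two reporting conventions are fixed here because the source defines
neither:

* **RD degrees of freedom.** RD = sqrt(SSE/(n − k − 1)), the residual
  standard deviation of the fit with k covariates. At n = 232 the
  difference between the n, n − 1 and n − 3 denominators is under 0.7%,
  well inside every tolerance used in the package's checks.
* **Rendered precision.** `render_equation()` folds the gender coefficient
  into per-sex intercepts and rounds registry-style — slopes to 3
  significant figures, intercepts to 4 — the precision the published
  table itself carries (52.6 vs 2788). Full precision is kept internally
  and `digits = NULL` disables rounding.

`fit_ols()` delegates the algebra to `stats::lm` (QR decomposition) and
layers the R²/RD bookkeeping on top; rank deficiency is reported as an
error naming the collinear columns rather than silently dropping them.
The test suite checks the fitter against an explicit normal-equations
solve on random small problems, so the wrapper and the oracle stay
independent routes to the same numbers.

## The validation battery

For an equation evaluated on a cohort with measured BMR,
`agreement_stats()` reports:

* **bias** = mean(predicted − measured). The sign convention follows the
  source's usage (a positive difference is an overestimation, and its
  agreement plots are labelled "predicted − measured").
* **SD of differences**, and **limits of agreement** = bias ± 2 SD. The
  multiplier is exactly 2 — the definition the source states — not the
  1.96 many Bland-Altman implementations use; `loa_k` makes it
  configurable. For Normal differences the ±2 SD band covers 95.45% of
  pairs, and the suite checks that coverage by simulation.
* a two-sided **paired t-test**, **R²** as the squared Pearson correlation
  of measured and predicted, and the **difference-vs-average regression**
  (slope, its p-value, R²) used to flag directional bias.

Degenerate inputs are handled explicitly rather than left to warnings: if
predictions equal measurements exactly, bias and SD are 0, the limits
collapse, R² is 1 and the t-test p is `NA` (the statistic is undefined);
a zero-variance difference vector reports a Bland-Altman slope of 0 with
`NA` inference.

`accuracy_classify()` applies the ±10% rule: accurate when
|predicted − measured| ≤ 0.10 × measured, with the boundary counted
accurate ("within ±10%"); beyond it the pair is an over- or
underestimate. The three classes partition every pair, so the percentages
sum to 100 before rounding; reports render whole percentages while JSON
output keeps full precision. `accuracy_breakdown()` tabulates the three
percentages overall and in the two BMI strata, reporting empty strata as
absent (`NA`) rather than zero. `evaluate_equations()` runs the battery
over a registry and ranks by overall accuracy (ties by absolute bias);
subjects outside an equation's age bands are skipped and counted under a
`policy = "skip"` default, or fail fast with `policy = "fail"`. P-values
are reported without multiple-testing adjustment, as is conventional in
these comparisons.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` describes a population by per-sex sample sizes and
weight/height/age moments, plus the measured-BMR model

$$\mathrm{BMR}_m = 1960 + 52.6\,W + 828\,G + \varepsilon,\qquad
\varepsilon \sim N(0, 534^2)\ \mathrm{kJ/d},$$

the mean structure and residual SD of the calibration study. The
`cross_sectional` preset carries that study's moments (121 men:
79.2 ± 14.9 kg, 171.7 ± 5.9 cm, 32.3 ± 9.9 y; 111 women: 66.1 ± 16.1 kg,
159.9 ± 6.2 cm, 33.4 ± 11.2 y); `cross_validation` carries the
independent validation group (26 men, 44 women). Sex is sampled as fixed
counts, not Bernoulli draws, matching the designs and removing a variance
source. Under these defaults the implied population SD of measured BMR is
sqrt(1112² + 534²) ≈ 1234 kJ/d and the weight+gender R² is ≈ 0.81 —
exactly the summary statistics the study prints — which is what makes the
generator a useful test bed: parameter-recovery checks have analytic
targets.

Deliberate modelling choices, with their consequences:

* **Untruncated Normal covariates by default.** The observed covariate
  ranges are carried in each preset, and `truncate = TRUE` applies
  rejection sampling against them, but the default leaves weight and
  height untruncated. Truncating at the observed ranges is not innocuous:
  the women's minimum weight sits only ~1.7 SD below the women's mean, and
  double truncation there cuts the women's weight variance by about 20%,
  dragging the predicted-BMR SD from ≈1112 to ≈1031 kJ/d and the
  population R² from ≈0.81 to ≈0.79. A generator that truncates by
  default would therefore fail to reproduce the very moments it is
  parameterised by; printed sample ranges are order statistics of the
  data, not population bounds, and are treated as such. Age is the
  exception: it does not enter the BMR model, and subjects must be
  adults, so age is always rejection-sampled into the preset's observed
  range. Weight and height are likewise always required to be positive —
  a physiological floor about four SDs out, with negligible effect on
  moments.
* **Independence within sex.** Weight, height and age are sampled
  independently (the sources report no covariance structure), with an
  optional within-sex weight–height correlation `wh_corr` (default 0) for
  realism experiments. The consequence is that per-subject BMI moments
  only approximately match the observed BMI distribution, so BMI-stratified
  accuracy checks carry wide tolerances.
* **Homoscedastic Normal residuals.** Only an overall residual SD is
  reported by the study, so the generator cannot know the true residual
  shape (skew, heteroscedasticity by body size). The ±10% accuracy rate
  is sensitive to exactly that shape: under the homoscedastic-Normal
  model the Singapore equation's expected accuracy is about 75%, a little
  below the observed 78%, and the package's checks allow for that gap.

Passing tests therefore demonstrate correct arithmetic and faithful
recovery of the stated population structure; they do not demonstrate that
real gas-exchange data or real anthropometry behave Normally.

`generate_gas_series()` builds hood traces for calorimetry tests by
inverting the Weir formula at a chosen respiratory quotient (RQ,
default 0.85) so the steady segment encodes a known true BMR, prepending
an exponentially decaying habituation transient (default amplitude 15%,
nominal duration 4 min; the time constant is `transient_minutes`·60/3 s,
so about 5% of the transient remains at its nominal end), and applying
per-sample multiplicative Normal noise (default CV 3%, a typical hood
variability). The generator and the processing chain are exact inverses
at zero noise, and at default noise the chain recovers the true BMR
within 1% — both are tested properties. The generator does not attempt
RQ physiology, drift from analyser warm-up, or subject movement
artefacts; it exists to make the processing chain testable, not to
simulate a calorimeter.

## Problem sizes and numerical conventions

The package's own calibration checks (test suite and
`scripts/acceptance.R`) use 200 replicate cohorts of n = 232 for the
regression-statistic recoveries, 200 seeded replicates for the stepwise
selection-frequency property, 10,000 simulated pairs for the
limits-of-agreement coverage check, and series of up to 400 samples for
the exhaustive steady-state oracle comparison. These sizes put the
Monte-Carlo standard errors comfortably inside the tolerances being
checked (e.g. the cross-cohort SE of mean R² at 200 replicates is about
0.001 against a ±0.01 band) while keeping a full run in the tens of
seconds on a single core.

Other conventions, gathered in one place: all energies are kJ/d
internally with kcal only at display time (4.184 kJ/kcal); CSV dialect is
comma-separated, dot-decimal, UTF-8 with headers; equation registries
serialise to CSV/JSON/YAML at full precision and round-trip bit-identically
at registry precision; cohort CSVs round-trip numerics to better than
1e-9 relative; every CLI run writes a manifest (package version,
subcommand, flags, seed) sufficient to reproduce its outputs
byte-for-byte.

## Known limitations

* The seven registry equations are the comparison set of the calibration
  study; other published equations (Schofield, FAO/WHO/UNU, equations on
  body composition) are out of scope.
* The calorimetry module consumes VO2/VCO2 directly; reconstruction from
  flow rate and gas fractions, analyser calibration and ethanol-burn QC
  are instrument territory and not modelled.
* The generator's independence and homoscedasticity assumptions are
  simplifications, as discussed above; conclusions about BMI-stratified
  behaviour on real data should not lean on it.
* Stepwise entry/exit thresholds of the original derivation software are
  unknown; forward selection at p < 0.05 is a documented assumption, not
  a reconstruction.
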