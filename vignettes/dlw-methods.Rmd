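---
title: "Methods: doubly labelled water energetics, water turnover and activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubly labelled water energetics, water turnover and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlwenergetics)
```

## The measurement model

The doubly labelled water (DLW) method doses a participant with water
enriched in two stable isotopes, deuterium (as ²H₂O) and oxygen-18 (as
H₂¹⁸O). Both tracers equilibrate with body water and are then eliminated:
deuterium leaves only as water, while oxygen-18 leaves both as water and as
CO₂ (through the carbonic anhydrase equilibrium). The difference between the
two elimination rates therefore measures CO₂ production, and with an assumed
diet-level respiratory quotient (the food quotient, FQ) CO₂ production
converts to total energy expenditure (TEE). The deuterium kinetics alone
measure water turnover (WT), the litres of body water replaced per day.

### Isotope kinetics: the slope-intercept method

After dosing, excess enrichment (enrichment above the participant's pre-dose
baseline) decays mono-exponentially, $E(t) = A e^{-kt}$. `fit_elimination()`
fits unweighted ordinary least squares of $\ln E$ on time over the post-dose
samples; the elimination rate $k$ (units: per day — all times in this package
are days) is minus the slope, and the zero-time intercept $A = e^{b_0}$ is
the excess enrichment the dose would have produced at the instant of dosing.
`dilution_space_from_dose()` converts $A$ into the dilution space
$N = n_\text{dose}/A$ (mol), where $n_\text{dose}$ is the moles of labelled
water administered (dose mass × label mass fraction / molar mass of the
labelled species; 20.0231 g/mol for ²H₂O, 20.0148 g/mol for H₂¹⁸O).

The canonical internal enrichment unit is mole-fraction excess; ppm-excess
inputs are declared in `dlw_config(enrichment_unit = "ppm_excess")` and
converted by 10⁻⁶. We chose unweighted log-linear OLS because it is the
standard slope-intercept estimator; weighting schemes for heteroscedastic
enrichment error are out of scope. If several pre-dose baselines are present
they are averaged with a warning; post-dose samples at or below baseline are
rejected by name rather than silently dropped, since a non-positive excess
usually means a sample mix-up.

### From kinetics to physiology: the two-pool equations

With $N_D$, $N_O$ the deuterium and oxygen-18 dilution spaces (mol) and
$k_D$, $k_O$ the elimination rates (per day), the pipeline computes

* corrected dilution space: $N_\text{corr} = (N_D/1.043 + N_O/1.007)/2$ —
  each space overestimates body water by a known factor (≈4.3% for ²H
  because of exchange with non-aqueous hydrogen, ≈0.7% for ¹⁸O);
* total body water: $TBW = 0.01802 \, N_\text{corr}$ kg;
* fat-free mass: $FFM = TBW/0.732$ (hydration constant of lean tissue),
  fat mass $FM = \text{body mass} - FFM$;
* CO₂ production, with $\Delta = 1.007 k_O - 1.043 k_D$:
  $rCO_2 = (N_\text{corr}/2.078)\,\Delta - 0.0246 \cdot 1.05\, N_\text{corr} \Delta$
  mol/day (the second term removes fractionated gaseous water loss), and
  $rCO_2$ in litres/day is 22.26 × mol/day;
* TEE $= rCO_2\,[\text{L/day}] \times (1.106 + 3.94/FQ)$ kcal/day — a
  Weir-type energy equivalent; at the default $FQ = 0.86$ it is 5.687
  kcal per litre CO₂;
* water turnover: $WT = 0.01802 \times 1.043 \times k_D N_D / 0.99$
  litres/day, the 0.99 being the evaporative fractionation correction.

All constants live in a single `dlw_config()` object. FQ and the hydration
constant are the two a practitioner may want to override: FQ = 0.86
corresponds to fats supplying roughly 30% of dietary energy, and a
lower-fat diet shifts computed TEE down by 3–5%. `process_cohort()` applies
the chain to a whole cohort, isolating per-row failures (a zero dilution
space, a rate pair with $\Delta \le 0$) so that one corrupt record does not
abort the cohort. Computation is done in full double precision; rounding to
4 significant figures happens only in `write_cohort_csv()`.

Numerical edge cases: at the exact boundary $1.007 k_O = 1.043 k_D$ the CO₂
production is legitimately zero, so `co2_production()` tolerates rounding
down to $\Delta \ge -10^{-10}$ and clamps it to zero; genuinely reversed
rates raise an error naming both rates. Negative fat mass is passed through
with a warning by default (no row of the packaged cohort triggers it);
`negative_fm_policy = "clamp"` clamps to zero for users who prefer a bounded
fat percent.

### The packaged cohort table and one misprinted row

`daasanach_cohort()` ships a 34-participant pastoralist cohort table
transcribed from the publication that motivated this pipeline (three
communities differing in pastoralist activity; 19 women, 15 men). Its
isotope columns are inputs and its printed FFM, fat%, WT and TEE columns are
golden values: on 33 of 34 rows the pipeline reproduces FFM within 0.05 kg,
WT within 0.006 L/day and TEE within 0.4%, comfortably inside what 4
significant-figure input rounding permits. One row (fixture id `D32`) is
internally inconsistent as printed — its dilution-space-ratio column reads
1.041 while its own printed ND and NO give 1.026, and no single-field
correction reconciles all its printed values — so the table flags it via the
`consistent` column and the row-wise reproduction tests exclude it. Its
inputs still flow through the pipeline normally.

## The statistical stage

TEE analyses work on the natural-log scale: `cohort_model_frame()` builds
lnTEE, lnFFM and lnFM from the *recomputed* (unrounded) pipeline outputs,
with FM always derived as body mass − FFM. Factors use treatment coding
with fixed reference levels (sex = F, community = Illeret,
population = Daasanach), matching how the published coefficient tables are
laid out. `fit_cohort_model()` is ordinary least squares via `stats::lm`,
reporting coefficient estimates, standard errors, two-sided t-test p-values
and adjusted $R^2$ — the model-selection criterion used here is adjusted
$R^2$ alone (no AIC machinery), mirroring the source analysis. On the
packaged cohort, lnTEE ~ lnFFM + lnFM + sex gives adjusted $R^2$ = 0.646
and an lnFFM elasticity of 1.32, and the nested model family preserves the
published adjusted-$R^2$ ordering.

`residual_anova()` re-uses the residuals of a fitted model as
covariate-adjusted values in a one-way ANOVA (e.g. community differences in
mass- and sex-adjusted TEE); on the packaged cohort the community effect is
F ≈ 0.57 on (2, 31) df, p ≈ 0.57. `kruskal_wallis()` wraps the
tie-corrected rank test for small-sample group comparisons such as daily
steps; the degrees of freedom follow the observed grouping (community × sex
cells with accelerometry give df = 3 here).

`predict_with_interval()` screens individual observations against an
external reference model supplied as serialised coefficients plus residual
scale: with the full $(X'X)^{-1}$ the prediction SE is exact
($\sigma\sqrt{1 + x'(X'X)^{-1}x}$); with only residual SD and $n$ it falls
back to $\sigma\sqrt{1+1/n}$, which ignores leverage and is slightly
anti-conservative far from the training mean — acceptable for screening
well-inside-range covariates, and the limitation is why the exact form is
preferred when available (`as_reference_model()` extracts it from any `lm`
fit). Coverage is validated by simulation: a reference model fitted to a
synthetic 1000-adult sample flags ≈95% of new draws from the same
generative model as inside their 95% prediction interval.

## Accelerometry

Count streams arrive as 10-s triaxial epochs. The pipeline crops to the
measurement window (`crop_to_window()`, half-open so abutting windows never
double-count an epoch), sums to 60-s epochs (`reintegrate()` — cut points
are defined per minute), and classifies each minute by the Euclidean vector
magnitude of the three axes: MVPA at ≥ 2690 counts/min, light activity at
[200, 2690), sedentary+nonwear below 200. The published cut-point wording
leaves 2689–2690 unassigned; we close the gap upward so the three classes
tile the whole count range — the choice affects at most integer-boundary
minutes.

Wear marking uses the de-facto standard zero-run rule: ≥ 90 consecutive
minutes of zero vector magnitude is non-wear, with nonzero spikes of ≤ 2
consecutive minutes absorbed into a surrounding zero run. The source
analysis names its wear-marking routine without parameters, so both are
configurable. Wear flags are *reported alongside* the class minutes rather
than used to null them: non-wear time stays inside the sedentary+nonwear
class, which is also how the published per-day summaries treat it. Days with
partial wear contribute to participant means (means are taken over days with
any wear).

## The synthetic-data generator

`generate_cohort()` draws truth in the causal order a physiologist would:
sex, then body mass and fat percent from sex-stratified truncated normals
(means 52.5/49.2 kg and 14%/25% for men/women, the packaged cohort's
summary statistics), then true TEE from a log-log linear model in FFM, FM
and sex (coefficients 3.35, 1.33, −0.16, −0.22) with log-scale residual SD
0.12, then true WT linear in TEE (3.07 + 0.002·TEE, residual SD 1.3 L/day,
floored at 2.5). The residual SDs are not published quantities; they were
chosen once so that fitted models on synthetic cohorts show adjusted $R^2$
near the published 0.65 (TEE) and 0.27 (WT) and were not tuned afterwards.

The isotope inputs are then *back-solved* rather than drawn: a
dilution-space ratio from N(1.041, 0.008) truncated to [1.00, 1.07] fixes
$N_D$ and $N_O$ from the body-water pool, $k_D$ solves the WT equation and
$k_O$ the TEE equation. Running the pipeline on the generated inputs
therefore reproduces the truth to machine precision — the generator and the
analysis are exact inverses, which turns every downstream stage into a
testable round trip. `generate_enrichment_series()` extends the loop to the
kinetics stage (mono-exponential washout from the dose with multiplicative
log-normal measurement noise), and `generate_accel_stream()` produces
bout-structured 10-s count streams whose per-day class minutes and steps
match the requested profile exactly, with optional labelled non-wear blocks
for recovery checks. All generators are pure functions of (seed, config);
`participant_seed()` fans a global seed out per participant by a stable
string hash.

What the generator does *not* emulate: seasonal variation in TEE or WT,
within-day isotope enrichment structure beyond the mono-exponential (no
multi-compartment kinetics), correlated measurement error between the two
isotopes, accelerometer non-linearities or spurious high-frequency counts,
and any mechanistic link between activity profile and energy expenditure.
Passing tests on synthetic data therefore validate the estimators and the
algebra, not the biological assumptions (hydration constant, FQ,
mono-exponential washout) that real data would stress.

## Problem sizes and reproducibility

The validation suite uses cohort sizes of 50–500, 300–400 Monte-Carlo
replicates for kinetics bias checks, and 1000-row samples for
prediction-interval coverage — sizes at which the Monte-Carlo error is well
below the tolerances being asserted while the whole suite runs in well under
a minute. The numbered scripts under `analysis/` are the workflow interface
(derive the cohort table, fit the model family, summarise activity, run the
simulation checks); each is a thin driver over the exported functions and
writes its tables under `results/`. There is no shell CLI beyond these
scripts: the functions themselves are the programmatic surface.

## Known limitations

* The two-pool equations assume the printed physical constants; populations
  with unusual body-water compartmentalisation violate the fixed 1.043/1.007
  space factors.
* FQ is assumed, not measured; TEE scales by $(1.106 + 3.94/FQ)$, so a
  mis-specified FQ biases TEE multiplicatively (a closed-form factor that
  `process_cohort()` makes easy to re-run under alternatives).
* The slope-intercept method uses only two time points' worth of information
  efficiently when sampling is sparse; no plateau-method fallback is
  provided.
* Reference-model screening without $(X'X)^{-1}$ underestimates interval
  width at extreme covariates.
* Step counts and MVPA minutes are displacement-based and can miss load
  carrying, digging or climbing — activity summaries are a proxy, not a
  measurement of activity energy expenditure.
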