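# dlwenergetics

An R package for field human-energetics studies that use the doubly
labelled water (DLW) method. It takes isotope enrichment time series (or
pre-computed isotope summaries), estimates elimination kinetics by the
slope-intercept method, converts them to body composition, CO₂ production,
total energy expenditure (TEE) and water turnover (WT) with the two-pool
equations, and provides the cohort-level statistical stage used in
comparative energetics work: log-log regression of TEE on body composition,
residual-adjusted ANOVA, rank tests, group summaries, and screening of
individuals against an external reference model's 95% prediction intervals.
An accelerometry module converts triaxial count streams to daily steps and
activity minutes via vector-magnitude cut points, and a synthetic-data
generator with exactly invertible ground truth makes every stage testable
without any external data.

## The model

With dilution spaces `ND`, `NO` (mol) and elimination rates `kD`, `kO`
(per day) from the two isotopes:

```
Ncorr = (ND/1.043 + NO/1.007) / 2                 corrected dilution space (mol)
TBW   = 0.01802 * Ncorr                           total body water (kg)
FFM   = TBW / 0.732                               fat-free mass (kg)
Δ     = 1.007*kO − 1.043*kD
rCO2  = (Ncorr/2.078)*Δ − 0.0246*1.05*Ncorr*Δ     mol/day  (×22.26 → L/day)
TEE   = rCO2[L/day] * (1.106 + 3.94/FQ)           kcal/day (FQ = 0.86 default)
WT    = 0.01802 * 1.043 * kD * ND / 0.99          litres/day
```

All constants sit in one `dlw_config()` object; the food quotient and the
hydration constant are user-overridable.

The package ships a 34-participant semi-nomadic pastoralist cohort table
(`daasanach_cohort()`, transcribed from the publication that motivated the
pipeline) whose isotope columns are inputs and whose printed derived columns
serve as golden values.

## Worked example

```r
library(dlwenergetics)

inp <- cohort_inputs()                       # packaged cohort, input schemas
derived <- process_cohort(inp$participants, inp$isotopes)
derived[derived$participant_id == "D01",
        c("ffm_kg", "fat_pct", "tee_kcal_day", "wt_l_day")]
#>    ffm_kg  fat_pct tee_kcal_day wt_l_day
#>  36.20718 24.56838     2167.948 6.630304

frame <- cohort_model_frame(derived)
fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), frame)
#> lnTEE ~ lnFFM + lnFM + sex  (n = 34)
#>         term estimate     se     t        p
#>  (Intercept)    3.380 0.8880  3.81 6.44e-04
#>        lnFFM    1.320 0.2250  5.87 2.01e-06
#>         lnFM   -0.166 0.0713 -2.32 2.72e-02
#>         sexM   -0.220 0.0707 -3.12 4.01e-03
#> R2 = 0.678, adjusted R2 = 0.646
```

The first participant's 48 kg body mass resolves into 36.2 kg fat-free mass
(24.6% fat), 2168 kcal/day TEE and 6.63 L/day water turnover — matching the
published values for that row to their printed precision. The regression
says TEE scales with lean mass with an elasticity of ~1.3 in this cohort,
with a negative fat-mass adjustment and lower TEE in men at a given body
composition.

The numbered scripts under `analysis/` run the full workflow (cohort
derivation, the regression family and group comparisons, accelerometry
summaries, simulation checks) and write their tables under `results/`:

```sh
Rscript analysis/01_dlw_cohort.R
Rscript analysis/02_cohort_models.R
Rscript analysis/03_activity.R
Rscript analysis/04_simulation_checks.R
```

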