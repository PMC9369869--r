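# metscreen

Screening indexes for metabolic syndrome in children and adolescents with
severe obesity.

## The problem

Pediatric severe obesity (BMI ≥ 3 standard-deviation scores above the age-
and sex-specific reference mean) carries a high risk of metabolic syndrome
(MetS): under the International Diabetes Federation (IDF) pediatric
definition, abdominal obesity plus at least two of high triglycerides, low
HDL cholesterol, elevated blood pressure, and elevated fasting glucose.
Clinicians want the *simplest* measurement that screens for MetS in this
population. `metscreen` implements, as a reusable and fully tested pipeline,
the comparison of seven candidate predictors:

| index | formula | needs |
|---|---|---|
| BMI | weight / height² (kg/m²) | scale, stadiometer |
| BMI-SDS | (BMI − ref mean)/ref SD, or the LMS z-score ((BMI/M)^L − 1)/(L·S) | + growth chart |
| TMI | weight / height³ (kg/m³) | scale, stadiometer |
| WtHR | waist / height (cm/cm) | + tape measure |
| TG/HDL | triglycerides / HDL-C (mmol/mmol) | fasting lipids |
| CMI | WtHR × TG/HDL | both |
| VAI | sex-specific: WC/(39.68 + 1.88·BMI) · TG/1.03 · 1.31/HDL (male); WC/(36.58 + 1.89·BMI) · TG/0.81 · 1.52/HDL (female), lipids in mmol/L | both |

The pipeline: synthetic-cohort simulation (Gaussian copula over log-normal
marginals) → index panel → rule-based IDF MetS classification → age
standardization of each index by polynomial quantile regression (z =
(y − q̂₀.₅(age)) / ((q̂₀.₇₅(age) − q̂₀.₂₅(age))/1.349)) → per-sex ROC curves
with DeLong AUC inference, Youden-optimal cutoffs and cutoff-level
diagnostics (sens/spec/PPV/NPV/PLR/NLR with CIs) → descriptive and
association statistics (rank tests, Spearman correlations, age-adjusted
logistic odds ratios) → age-by-sex cutoff trend with bootstrap bands.

Because subject-level clinical data of this kind are not openly deposited,
the package ships a calibrated synthetic-cohort generator that emulates the
study population (n = 1065, 502 boys / 563 girls, ages 10–17, BMI-SDS ≥ 3,
~30% MetS prevalence) so every stage is exercisable end to end with no
download.

## Worked example

```r
library(metscreen)

spec   <- cohort_spec(n_total = 1065, seed = 1)   # calibrated defaults
ref    <- generate_reference(spec)                # synthetic growth reference
cohort <- generate_cohort(spec)
panel  <- compute_panel(cohort, ref)              # the seven indexes
cls    <- classify_mets(panel, ref)               # IDF flags + MetS

subset(component_prevalence(cls), flag %in% c("mets", "low_hdl") & group == "all")
#>       flag group count    n  pct
#> 7  low_hdl   all   446 1065 41.9
#> 16    mets   all   302 1065 28.4

sel <- cls$sex == "M"
lab <- as.integer(cls$mets[sel])
z   <- standardize_by_age(cls$tg_hdl[sel], cls$age[sel])$z  # age-adjusted
rc  <- roc_curve(z, lab)
rc
#> ROC curve: 167 positives / 335 negatives, AUC = 0.829 (95% CI 0.792-0.867)

yc <- youden_cutoff(rc)
confusion_metrics(z, lab, yc$cutoff)
#> Diagnostic metrics at cutoff 0.5096 (wilson_subgroup CIs)
#>   sensitivity: 0.659 (0.584-0.726)
#>   specificity: 0.857 (0.815-0.890)
#>   PPV:         0.696 (0.621-0.763)
#>   NPV:         0.834 (0.791-0.870)
#>   PLR: 4.6   NLR: 0.4

zb <- standardize_by_age(cls$bmi[sel], cls$age[sel])$z
cmp <- delong_compare(z, zb, lab)
#> TG/HDL vs BMI (boys): AUC 0.829 vs 0.573, DeLong p = 3.9e-16
```

The lipid ratio screens MetS in this simulated severely obese cohort with
AUC ≈ 0.83, while BMI — already extreme in everyone by construction — is
barely better than chance; the DeLong test confirms the difference. The
prevalence table reports exact counts with one-decimal percentages.

The whole pipeline, with all eight artifact files plus a reproducibility
manifest, is one call:

```r
run_pipeline(pipeline_config(spec = cohort_spec(n_total = 2000, seed = 7),
                             seed = 7, out_dir = "run"))
```

or from a shell, `inst/cli/metscreen all --n 2000 --seed 7 --out run`.

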