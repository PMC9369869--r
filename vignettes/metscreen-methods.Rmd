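---
title: "Methods: evaluating MetS screening indexes in pediatric severe obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating MetS screening indexes in pediatric severe obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

`metscreen` evaluates seven anthropometric/biochemical indexes as screening
predictors of IDF-defined metabolic syndrome (MetS) in children and
adolescents with severe obesity. This vignette is the package's own account
of the underlying models, the tunable parameters, the numerical choices, and
the limits of what its tests demonstrate.

## 1. The classification target: pediatric IDF MetS

A subject is labelled MetS when abdominally obese **and** showing at least
two of four components. All thresholds operate on the mg/dL scale exactly as
defined, inclusive (`>=`) for risk thresholds and strict (`<`) for low HDL:

* abdominal obesity — waist circumference (WC) at or above the sex/age 90th
  percentile below age 16, and at or above 94 cm (males) / 80 cm (females)
  from age 16 on;
* high triglycerides — TG ≥ 150 mg/dL (1.7 mmol/L);
* low HDL-C — HDL < 40 mg/dL for males at any age and females under 16,
  HDL < 50 mg/dL (1.29 mmol/L) for females from 16 on;
* high blood pressure — SBP ≥ 130 or DBP ≥ 80 mmHg;
* high fasting glucose — ≥ 100 mg/dL (5.6 mmol/L).

The IDF wording ("< 16 years", "> 16 years") leaves exactly-16 unassigned;
the package assigns age ≥ 16 to the adult branch, the conventional reading,
and exposes `adult_at` so the alternative is one argument away. Molar
conversions are fixed at 88.57 (TG), 38.67 (cholesterol) and 18.02 (glucose)
mg/dL per mmol/L.

## 2. The index panel

BMI, TMI, WtHR and TG/HDL are ratio formulas. BMI-SDS supports two
reference modes, because published growth references come in both forms: a
plain `(BMI - mean)/SD` z-score and the Box-Cox LMS z-score
`((BMI/M)^L - 1)/(L S)` (log form at `L = 0`). The reference is indexed by
completed year of age (`floor(age)`), the usual chart convention. Real (e.g.
WHO) tables are user-supplied CSVs; the package never bundles them.

The visceral adiposity index deserves a note. The formula is frequently
typeset as `(WC/39.68 + (1.88 × BMI)) × (TG/1.03) × (1.31/HDL)`, which read
literally is dominated by the `1.88·BMI` summand and yields values in the
tens for ordinary adolescent inputs. The package implements the original
formulation `WC/(39.68 + 1.88·BMI) · (TG/1.03) · (1.31/HDL)` (and the female
analogue): on representative severely obese medians (male: WC 120, BMI 38.3,
TG 93, HDL 41 mg/dL) it returns 1.35, in the plausible 1-2 range, while the
literal parse exceeds 50. The test suite asserts both facts.

## 3. The synthetic cohort generator

No subject-level data are shipped or downloaded; the generator *is* the
study-conditions module, and its defaults are frozen.

**Marginals.** Each positive measurement (height, weight, WC, SBP, DBP,
glucose, TG, HDL, LDL, insulin) is log-normal with location `ln(median)` and
log-scale `log-IQR / (2·qnorm(0.75)) = log-IQR / 1.349`, matched per sex to
the median and quartiles of the emulated severe-obesity cohort
(`default_marginals()`). The log-normal respects positivity and the
right-skew that clinical chemistry shows; medians and quartile ratios are
matched in closed form. Age is uniform on [10, 17.99] years — the emulated
study reports only the range.

Two summaries required de-heaping: clinical BP is recorded to the nearest
2 mmHg and heights charted coarsely, so printed quartiles can collapse onto
the median (girls' SBP "120 (120–130)", DBP "80 (70–80)"), which no
continuous marginal can match. The defaults use nearby continuous values
(boys' DBP 77 (70–83); girls' SBP 122 (116–132), DBP 77 (70–83); heights
1.70 (1.63–1.77) m and 1.61 (1.56–1.66) m) chosen once so that the implied
exceedance frequencies reproduce the reported component frequencies, and so
that the implied BMI median (medians compose exactly in log space:
`med(W)/med(H)²`) lands on the reported per-sex BMI medians. Glucose is
treated as mg/dL throughout: the emulated cohort's glucose row is plainly on
that scale despite its printed unit label.

**Dependence.** A Gaussian copula couples the variables
(`default_copula()`): growth with age (age-height 0.70, age-weight 0.45),
strong adiposity coupling (weight-WC 0.80), moderate BP-adiposity and
BP-lipid links, TG-HDL at -0.40, insulin tracking adiposity and TG. The
matrix was calibrated **once** against the reported component frequencies
(high TG ≈ 11%, low HDL ≈ 45%, high BP ≈ 50%, high glucose ≈ 0.7%, MetS ≈
30%) and frozen; the acceptance suite then checks, over 10 seeds at
n = 5000, that downstream MetS prevalence lands within ±3 percentage points
of 30.4%. For a Gaussian copula the implied Spearman correlation is
`(6/π)·asin(ρ/2)`, which the fidelity test uses as a closed-form oracle.

**Internal consistency.** BMI is always derived from generated weight and
height — never drawn independently — so records cannot be anthropometrically
impossible; SBP > DBP holds by the marginal placement and is validated on
file input.

**The synthetic growth reference.** `generate_reference()` builds, per sex
and integer age 10-17, an LMS BMI reference (L = -1.6, S = 0.12, M set so
that the z = 3 boundary sits near the 0.2nd percentile of the generated BMI
distribution) and a WC 90th-percentile track rising linearly with age well
below the generated WC range. Consequences, both tested: the severe-obesity
filter (BMI-SDS ≥ 3.00, inclusive) retains ≥ 99% of generated subjects, and
≥ 99% flag abdominal obesity in both sexes — mirroring a cohort in which
essentially everyone meets the abdominal criterion. The negative L
compresses the far-right tail so synthetic BMI-SDS values sit in the
realistic 3.4-4.5 band; a linear mean/SD reference cannot deliver both that
magnitude and the ≥ 99% retention, which is why the synthetic reference uses
LMS mode (the mean/SD mode is exercised with hand-built references in the
tests). The reference is a synthetic stand-in, clearly labelled as such, not
a reproduction of any published chart.

**What the generator does not emulate.** Pubertal stage, ethnicity,
longitudinal growth, measurement heaping, missing data, and any skewness
beyond the log-normal's. Sex-specific dependence is also out: one copula
serves both sexes, so sex differences arise only through the marginals.
Passing tests therefore demonstrate correctness of the pipeline's logic and
calibration of its aggregate rates — not that real cohort data would yield
the same AUCs or cutoffs.

## 4. Age standardization by quantile regression

Index distributions drift with age, so raw values confound age with risk.
The package fits polynomial quantile curves (default degree 2, configurable)
at τ = 0.25, 0.5, 0.75 and retains the standardized residual

z = (y − q̂₀.₅(age)) / ((q̂₀.₇₅(age) − q̂₀.₂₅(age)) / 1.349),

location = fitted median, scale = normal-consistent fitted IQR. This is the
closest simple analogue of LMS location/scale standardization without a
skewness parameter. Fits are per sex, since the downstream ROC analysis is
sex-stratified. All seven indexes are standardized by default; whether a
purely biochemical ratio needs age adjustment is genuinely arguable, so
`standardize_biochemical = FALSE` switches TG/HDL to its raw scale.

**Numerics.** The pinball loss is minimized by Schlossmacher-style IRLS with
weights `|τ − 1{r<0}| / max(|r|, ε)`, ε = 1e-6 guarding the division.
Convergence is declared when the maximum coefficient change drops below
1e-8 **or** the relative objective decrease drops below 1e-10; the second
criterion matters because once residuals hit the ε floor the coefficients
creep at ~1e-6 per iteration while the objective is flat to ten digits — a
pure coefficient criterion at 1e-8 would need arbitrarily many iterations.
The cap is `maxit = 500` (a few hundred iterations are typical at
n ≈ 2000). Degenerate inputs error early: constant ages with degree ≥ 1,
constant values (zero scale), and fitted quartile curves that cross anywhere
on the observed age range (the error advises lowering the degree).
Coefficients are reported on the raw polynomial basis `1, age, age², ...`,
fine at degree ≤ 3 over ages 10-18.

## 5. ROC, Youden and diagnostic metrics

The ROC machinery is implemented from scratch, as it is the analytic core:

* the curve sweeps `score ≥ t` over all distinct observed scores plus a +∞
  sentinel, so it runs (0,0) → (1,1) with nondecreasing coordinates;
* AUC uses midranks, making it exactly the Mann-Whitney statistic
  (concordant pairs + half-ties) — asserted against a brute-force pair count
  at n ≤ 200, and against `pROC` as an independent implementation;
* AUC standard errors, CIs and paired comparisons use DeLong placement
  values; `delong_compare` is antisymmetric and exactly null under monotone
  transforms of a predictor;
* the Youden cutoff maximizes J = sens + spec − 1 with ties broken toward
  the smallest threshold, verified against an exhaustive sweep;
* cutoff-level metrics come from the 2×2 table, with PLR/NLR computed from
  unrounded proportions; empty denominators are flagged `not_calculable`,
  never imputed.

Two CI conventions are offered for the proportion metrics. The default
`wilson_subgroup` is the statistically standard Wilson score interval on
each metric's own denominator. `wald_total_n` instead computes
`p ± 1.96·√(p(1−p)/N)` with `N` the full per-group sample size — a
convention some published screening tables follow (its half-width at
p = 0.752, N = 563 is ≈ 0.036, matching that reporting style); it is
provided, clearly labelled, for replication rather than recommendation.

**Cutoff trend.** Per sex and completed year of age, the Youden cutoff of
raw TG/HDL is estimated within the stratum; a class-stratified bootstrap
(percentile method, default 1000 replicates, seeded) gives 95% bands, and
the per-age sex difference is tested by bootstrapping the cutoff difference.
Strata under `min_n = 30` subjects, or with a single outcome class, are
flagged and excluded rather than silently estimated.

## 6. Association statistics

Rank-based comparisons wrap the standard implementations: the two-sample
comparison is the Mann-Whitney U with midranks, tie correction and
continuity correction (`wilcox.test(exact = FALSE, correct = TRUE)`), the
k-group comparison is tie-corrected Kruskal-Wallis. Spearman's ρ is the
Pearson correlation of midranks with the t-approximation p-value, written
out so zero-rank-variance degeneracy is flagged explicitly. The outlier
screen flags |z| > 4.5 and only flags — exclusion is the caller's decision.

Odds ratios come from maximum-likelihood logistic regression
(`outcome ~ exposure + age`; IRLS is Newton-Raphson for the canonical logit
link; tolerance 1e-10, ≤ 50 iterations) with Wald CIs and Nagelkerke's
pseudo-R² = (1 − exp((D₁−D₀)/n)) / (1 − exp(−D₀/n)) ∈ [0, 1]. One-class
outcomes return `not_calculable` with reason "all observations have the same
response", and (quasi-)separation — fitted probabilities at 0/1 with a
diverging coefficient — is likewise refused, mirroring how such cells must
be reported in practice. Without the age covariate the binary-exposure model
is saturated, so the fitted OR equals the 2×2 cross-product ad/bc — the
closed-form oracle in the tests. The pipeline dichotomizes TG/HDL at the
sex-specific Youden cutoff of the raw ratio (consistent with the large OR
magnitudes such exposures produce); a continuous-exposure analysis is a
one-line variation via `logistic_or`'s inputs.

## 7. Pipeline and reproducibility

`run_pipeline()` emits the full artifact set (panel, classification,
descriptives, per-sex ROC coordinates, AUC comparison matrix, Youden
metrics, correlations, odds ratios, cutoff trend) plus `manifest.json`
recording the configuration, seed, package version and a digest of every
artifact; no timestamps enter any file, so identical configurations
reproduce byte-identical output. Every stochastic stage (generation,
bootstrap) seeds its own RNG and restores the caller's state. Report
formatting follows clinical screening-report conventions: counts exact, percentages
half-up to one decimal, PLR/NLR printed to one decimal, proportions to
three.

## 8. Problem sizes and what the tests show

The suite runs at deliberately modest sizes: marginal/copula fidelity and
identity-limit checks at n = 5000; quantile-regression recovery and coverage
at n = 2000; DeLong power and OR coverage at 200 Monte-Carlo replicates;
rank-test size at 1000 replicates; bootstrap null calibration at 100
replicates with 199 resamples; prevalence calibration over 10 seeds of
n = 5000. These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping the default run quick. What passing shows: the
formulas, rules and estimators are correct and internally consistent, and
the frozen generator reproduces the aggregate structure it was calibrated
to. What it cannot show: performance on real cohort data, whose dependence,
heaping and tails the generator only approximates.

## 9. Known limitations

* Synthetic BMI-SDS values cluster where the synthetic LMS reference puts
  them; they are not comparable to z-scores from any published chart.
* The copula is shared across sexes and has no age-varying dependence.
* Exact small-sample rank tests are out of scope: p-values are large-sample
  approximations.
* Wald logistic CIs are poor near separation; the package refuses those fits
  rather than repairing them (no Firth correction).
* The quantile curves are global polynomials; no spline or monotonicity
  constraint is imposed beyond the crossing check.
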