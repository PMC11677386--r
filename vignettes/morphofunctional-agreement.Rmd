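---
title: "Muscle biomarkers and method agreement: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle biomarkers and method agreement: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoagree)
```

## The problem

Skeletal muscle quantity and quality carry prognostic weight in oncology
and clinical nutrition, but the three techniques used to measure them at
the bedside or opportunistically — CT segmentation at the third lumbar
vertebra, whole-body bioelectrical impedance analysis (BIA), and
point-of-care muscle ultrasound (US) — report on different scales and
through different prediction equations. Before one technique can stand
in for another, two questions must be answered quantitatively: do paired
measurements agree (not merely correlate), and do the categorical
diagnoses built on them (muscle atrophy, myosteatosis, sarcopenia,
malnutrition) agree? This package implements that entire assessment
battery as reusable, tested code: equation evaluation, rule-based
diagnosis, and the agreement statistics, together with a synthetic
cohort generator so every stage is testable without patient data.

## Units, coding, and the equation layer

All storage is in canonical units: height in metres, muscle thicknesses
in millimetres, areas in cm², masses in kg, resistive quantities in Ω,
radiodensity in HU. Sex is coded once, `female = 0, male = 1`, and every
equation reads that code — no per-equation re-coding.

Each prediction equation adapter performs its own declared unit
conversion, so conversions are testable in isolation:

| Equation | Output | Height unit | Other conversions |
|---|---|---|---|
| Shen | MM (kg) = (0.166·SMA + 2.142)·1.06 | — | — |
| Mourtzakis | FFM (kg) = 0.30·SMA + 6.06 | — | — |
| Janssen | MM (kg) = 5.102 + 0.401·(H²/R) + 3.825·S − 0.071·A | **cm** | — |
| Kanellakis | FFM (kg) = 12.299 + 0.164·W + 7.287·S − 0.116·(R_z/H) + 0.365·(X_c/H²) + 21.570·H | **m** | — |
| Kotler | FFM (kg) = 0.88·((H^2.24/Z^0.63)/37.63) + 0.16·W − 3.96 | **cm** | — |
| USVALID (Fischer) | SMA (cm²) = −54.0 + 21.0·S + 0.4·W + 0.6·H + 15.0·Q | **cm** | Q: mm → cm |
| Refitted US model | SMA (cm²) = −74.04 + 12.03·Q + 0.56·W + 0.70·H + 18.86·S | **cm** | Q: mm → cm |

Two of these conventions deserve a note. The Janssen equation is often
reprinted without a height-unit footnote; the original publication uses
centimetres, and only centimetres produce adult-range masses (≈23 kg on
typical inputs, versus <10 kg with metres), so centimetres are adopted
and guarded by a unit test. The Kotler equation is published with
sex-specific coefficient pairs; the single printed form implemented here
is applied to both sexes, as flagged in its documentation. The mass SMI
attributed to Shen is interpreted as the Shen whole-body MM divided by
height squared. Derived indices are `SMI = value/H²` and
`SMG = SMI-CT × SMD`; note the cohort mean SMG is not the product of
the mean SMI and the mean SMD.

A consequence worth exploiting: the Shen, Mourtzakis, and both US
equations are *linear*, so they commute exactly with cohort means (and,
being monotone, with medians). Published cohort-level summaries of the
inputs therefore determine the cohort-level summaries of the derived
masses exactly — this identity is what `scripts/acceptance.R`
recomputes, and it holds to machine precision in the test suite.

`fit_sma_regression()` re-estimates the US→SMA model by ordinary least
squares on any cohort (predictors Q in cm, W, H in cm, S), reporting
adjusted R² = 1 − (1−R²)(n−1)/(n−p−1). On noiseless synthetic data it
recovers generating coefficients to ≤10⁻⁸ relative error; rank-deficient
designs raise an error rather than returning dropped terms.

## The diagnostic rule engine

Every diagnosis is a covariate-conditional threshold rule, and all
shipped rules share one convention: **a value strictly below its stratum
threshold is abnormal; the boundary value is normal**. Cut-off sets are
YAML documents (name, biomarker, strata, thresholds, citation), loaded
into a generic engine that

* matches each subject to exactly one stratum (ranges are `[min, max)`),
* raises an "unclassifiable" error for covariates outside every declared
  stratum — never a silent default,
* rejects overlapping strata at construction time.

Shipped sets cover CT atrophy (SMI-CT conditional on sex and BMI), CT
myosteatosis (SMD conditional on BMI), BIA atrophy (two sex-conditional
SMI-Janssen sets: a Spanish reference and the European consensus), and
US atrophy (sex-conditional rectus-femoris thickness and area). The US
thickness set prints its male threshold (9.66 mm) *below* the female one
(10.4 mm); this is implemented exactly as published and flagged as
unusual in the config. Two tables could not be bundled from their
sources: the appendix-only sex-specific SMI thresholds and the normative
handgrip centiles. Both ship as clearly labelled **synthetic
placeholders** (`vanvugt_smi_synthetic.yaml`, `grip_p10_synthetic.yaml`)
that users must replace for clinical use; because the engine is generic,
replacement changes nothing else.

The composite rules:

* **Dynapenia** — handgrip strictly below the age/sex 10th percentile of
  the normative table.
* **Sarcopenia** — the conjunction of an atrophy flag (under any
  definition) and dynapenia; if either is unresolved, so is sarcopenia.
* **GLIM malnutrition** — worst severity across the phenotypic criteria.
  Involuntary weight loss: moderate >5% within 6 months or >10% beyond;
  severe >10% within 6 months or >20% beyond; voluntary loss never
  counts. Low BMI: moderate <20 (age <70) or <22 (≥70); severe <18.5
  (<70) or <20 (≥70). The etiologic criterion is assumed satisfied,
  appropriate for a cohort defined by an inflammatory disease. Age
  exactly 70 is assigned to the older band, matching the usual "70 or
  older" grouping; some sources write "<70 / >70", which leaves 70
  undefined.
* **Obesity** — BMI ≥ 30 (any WHO obesity grade). Some study reports
  print "BMI ≥ 20" for obesity; that contradicts their own obesity
  counts by BMI band and is treated here as a typo for 30.

The engine is verified two ways: a brute-force rule-scan oracle
reimplements classification with plain nested conditions and is compared
branch-by-branch (probing just below, at, and just above every
threshold), and a grid sweep over sex × BMI × age asserts no
unclassifiable gaps inside the declared ranges.

## The agreement battery

`bland_altman(reference, index)` takes differences as
**reference − index**, so a positive bias means the index method
*underestimates* — the convention that makes "index underestimated by
1.5 kg" read directly off the output. It reports the mean difference
(bias), sample SD of differences, limits of agreement bias ± 1.96·SD, a
least-squares regression of differences on pairwise means
(dose-dependent bias) with its slope p-value, and the count outside the
limits. The identity bias = mean(reference) − mean(index) holds exactly
for any input, which is what lets printed group means validate printed
biases.

`lin_ccc()` implements the concordance correlation coefficient
ρc = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²) with population (1/n) moments
per the original definition, a Fisher-z confidence interval using the
standard asymptotic variance, and the conventional qualitative bands
(>0.99 near perfect, 0.95–0.99 substantial, 0.90–0.95 moderate, <0.90
poor). ρc never exceeds |r| and equals r exactly at matched means and
variances; both properties are tested, and ρc is checked against the
bivariate-normal closed form 2ρ/(2 + δ²) by simulation at n = 10⁵.

`cohen_kappa()` computes unweighted kappa from the k×k table with the
large-sample null-variance p-value; it is verified against exhaustive
direct computation on every 2×2 table with n ≤ 6.

`compare_location()` reproduces the normality-gated testing scheme used
in method-comparison practice: paired samples get a paired t-test when
the differences pass a Shapiro–Wilk gate (α = 0.05), else a Wilcoxon
signed-rank test with zero differences dropped (Wilcoxon's original
convention — documented because zero handling materially changes
small-sample p-values). Independent samples get a pooled t-test when
both groups pass the gate *and* Levene's test finds no
heteroscedasticity, else the Wilcoxon rank-sum test. The rank-sum choice
is a deliberate correction: a signed-rank test is undefined for
independent groups of unequal size even though some protocols name it
for both cases. Above n = 5000 the Shapiro–Wilk statistic is undefined,
so the gate is evaluated on 5000 evenly spaced order statistics — a
deterministic thinning that preserves distribution shape. The gated
procedure holds its type-I error at ≈0.05 over 2000 null replicates in
the acceptance suite.

## The synthetic cohort generator

The generator is the package's stand-in for unavailable patient data,
and its defaults *are* the study conditions: n = 156, 48.1% female, ages
drawn from a shifted gamma on [50, 90) with median ≈65, height by sex
(1.58/1.70 m ± 0.06), log-normal BMI with median 27.3 and IQR ≈5.7
kg/m². A single latent muscularity factor M ~ N(0, 1) drives every
muscle channel: L3-SMA increases in M, sex, and weight (female ≈103,
male ≈146 cm²); BIA resistance decreases in M and weight; reactance
follows resistance and M, with phase angle θ = tan⁻¹(X_c/R_z) in degrees
and Z = √(R_z² + X_c²) derived so the raw BIA quartet is internally
consistent; US thicknesses and handgrip increase in M; radiodensity
declines with age and BMI and is clamped to the segmentation window
[−29, 150] HU. Channel loadings were set once, by moment-matching the
published cohort marginals and the sign pattern of the published
correlation matrices (resistance vs muscle area ≈ −0.65, phase angle vs
handgrip ≈ +0.5), and are not tuned thereafter.

This single-factor design is the *minimal* structure reproducing that
sign pattern. It does not model treatment effects, tumour stage,
fluid-balance artifacts, longitudinal change, or any non-Gaussian tail
behaviour of real measurements, and its missingness injection is
uniform at random — so passing tests demonstrate that the pipeline's
arithmetic and logic are correct under realistic correlation structure,
not that any clinical conclusion transfers to real cohorts.

`make_paired_channel()` adds a copy of a column plus a known additive
bias and Gaussian noise; the full pipeline (derive → agree) recovers an
injected bias within 3·SD/√n and the SD of differences within 10% at
n = 10⁴, which is the package's end-to-end correctness check for the
Bland–Altman path.

## Numerical and scale choices

* Computation is at full floating precision; only comparisons against
  published tables round, at the tables' precision (1 decimal for
  biomarkers, 3 for correlations and kappa).
* Test problem sizes: closed-form and oracle checks run at n ≤ 200;
  Monte-Carlo recovery checks at n = 10⁴; the CCC closed-form and
  limits-of-agreement coverage checks at n = 10⁵; the type-I error check
  at 2000 replicates of n = 30 per group. These sizes put Monte-Carlo
  error well inside each stated tolerance while keeping the default
  suite around fifteen seconds.
* Seeds: every stochastic test fixes its seed; cohort generation is a
  pure function of (spec, seed) and restores the caller's RNG state.
* Degenerate inputs fail loudly everywhere: constant vectors in
  correlation or normality tests, rank-deficient regression designs,
  covariates outside declared strata, kappa when both raters are
  constant and equal.

## Known limitations

* The proprietary device equations (Talluri MM/FFM) are accepted only as
  optional pre-computed input columns and never computed.
* The Kotler single-form implementation and the two synthetic
  placeholder tables (SMI thresholds, grip centiles) must be replaced
  with source values before any clinical interpretation.
* No multiple-testing correction is applied anywhere, matching the
  practice the battery reproduces; with dozens of pairwise analyses,
  individual p-values should be read accordingly.
* Quantitative agreement analyses use pairwise-complete records with no
  imputation.
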