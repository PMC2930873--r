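---
title: "Methods: score construction, interaction models, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score construction, interaction models, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(activgps)
```

This vignette documents the statistical model the package implements,
the choices made where the design was genuinely open, what the
synthetic-cohort generator does and does not emulate, and the numerical
conventions.  It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The model

The genetic predisposition score (GPS) is the unweighted count of
BMI-increasing alleles over a 12-SNP panel; with $g_{ij} \in \{0,1,2\}$
the risk-allele dosage of subject $i$ at SNP $j$,
$\mathrm{GPS}_i = \sum_j g_{ij}$ (range 0–24).  Subjects missing at most
3 genotypes have each missing dosage replaced by that SNP's mean dosage
among genotyped subjects of the analysis cohort, making the score
fractional; with more than 3 missing the score is undefined and the
subject drops from score analyses.

Physical activity (PA) is an ordinal index 0–3 built from occupational
class and daily recreational activity hours (weekly summer and winter
hours averaged, divided by 7).  The cross-sectional model is

$$\mathrm{BMI}_i = \beta_0 + \beta_g \mathrm{GPS}_i + \beta_a \mathrm{PA}_i
  + \gamma\, \mathrm{GPS}_i \times \mathrm{PA}_i
  + \beta_1 \mathrm{age}_i + \beta_2 \mathrm{age}_i^2 + \beta_3 \mathrm{sex}_i
  + \varepsilon_i,$$

fit by OLS; obesity (BMI ≥ 30 vs normal weight 18.5 ≤ BMI < 25) and
overweight (≥ 25 vs normal) use the analogous logistic model.  The
interaction coefficient $\gamma$ is reported from the model containing
both main effects.  Stratified per-allele effects refit the adjusted
model within each PA level (and in the combined-active stratum, levels
1–3), dropping the PA covariate, which is constant (binary coding) or
nearly redundant within a stratum.  The longitudinal outcome is the
annual BMI change $(\mathrm{BMI}^{fu} - \mathrm{BMI}^{0})/\Delta t$,
modelled on GPS × PA adjusted for age, age², sex and baseline BMI.

## Open design points and how they were resolved

* **PA coding.**  Activity enters models as a single linear ordinal
  term (one coefficient per level increase), because the analysis this
  package reproduces reports one trend effect per activity level; the
  binary combined-active vs inactive coding is available everywhere as
  an option.  Categorical-dummy coding was considered and rejected as
  the default to keep one interpretable interaction coefficient.
* **The activity classification has one unspecified cell** (standing
  job with 0.5–1.0 h/d of recreational activity).  We classify standing
  with ≥ 0.5 h/d as *active*, the unique monotone fill: more
  recreational hours never lower the level, a more physical job never
  lowers it.  The classification is tested exhaustively cell by cell
  and as a monotonicity property.
* **Required phenotypes for exclusion rule 2.**  Recreational hours are
  a *required* phenotype for sedentary, standing and physical
  occupations (the level depends on them) but not for heavy manual
  work, which is active regardless.
* **Substitution mean provenance.**  The per-SNP substitution mean is
  computed on the post-exclusion analysis cohort, sex-pooled (no
  sex-specific score is ever reported).
* **HWE test.**  1-df chi-square against $p^2 : 2pq : q^2$ at the
  sample allele frequency, no continuity correction — the standard
  genotyping-QC form at cohort sample sizes.  Monomorphic SNPs return
  p = 1 with a warning rather than an error, so QC can flag them via
  the report.  QC thresholds (call rate > 0.95, HWE p > 0.05) are
  strict inequalities.
* **Multiple testing in the per-SNP scan.**  Bonferroni over the SNPs
  actually tested; the source analysis names no specific method, and
  Bonferroni is the most conservative standard choice.
* **AUC machinery.**  AUC is the Mann–Whitney rank estimator with
  midrank ties (proved equal to trapezoidal ROC integration in the
  tests), computed in-sample on each stratum as the source analysis
  implies; a cross-validated variant sits behind `cv_folds`.  The CI is
  the Hanley–McNeil normal approximation.  The between-stratum AUC test
  is a stratified subject-level bootstrap (the original test is
  unnamed; DeLong would be the natural alternative and is out of
  scope).
* **Gram conversion rounding** is half-away-from-zero.  One published
  value (0.313 kg/m² → "904 g") is consistent only with truncation or
  extra unprinted digits (half-away gives 905); that single case is
  deliberately not an acceptance surface.

## The synthetic cohort: what it emulates

The generator draws, per subject: genotypes Binomial(2, $p_j$)
independently across 12 SNPs (exact HWE, no LD); an activity level from
the configured proportions (defaults 0.302/0.285/0.228/0.185, the
pooled baseline distribution of the cohort being emulated); age uniform
39–79; sex with 49% male; and baseline BMI from the cross-sectional
model above with a per-allele effect of 0.205 kg/m² at PA 0 declining
linearly by 0.0263 per level to 0.126 at PA 3, an activity effect of
−0.313 kg/m² per level, and Gaussian noise (SD 3.6 kg/m², chosen so the
marginal BMI SD is ≈ 3.7 as in the emulated cohort).  Occupation and
recreational hours are back-filled by drawing uniformly among the
(occupation, hours) cells consistent with the generative level, so the
classifier recovers the level exactly — only the derived level enters
any analysis.  Follow-up lies 3–4 years later with annual drift
N(0.05, 0.2²) kg/m²/y plus an optional per-allele drift (+0.006 at PA 0,
slope −0.004 per level), reproducing the longitudinal sign pattern
(genetic effect on weight gain positive in inactive, negative in active
subjects) whose published magnitudes are not reported; 41.6% of
subjects drop out of follow-up.  Waist circumference is affine in BMI
plus noise and exists only to exercise the waist exclusion filter.
Genotype missingness is a single independent per-call rate, 0.04 by
default, matching the emulated fraction of fully genotyped subjects
(0.96¹² ≈ 0.61); real missingness is overdispersed (2.7% of subjects
exceed 3 missing SNPs there, far more than independence predicts), so
the >3-missing branch is exercised by dedicated unit fixtures rather
than by default simulation.  The age effect (0.30·age − 0.0025·age²,
peaking near 60) contributes realistically little BMI variance; the
intercept 15.5 centres mean BMI near 26.2.

**What a green test does and does not establish.**  Simulated genotypes
are exactly HWE and mutually independent, missingness and dropout are
completely at random, and BMI errors are homoscedastic Gaussian.
Parameter-recovery and calibration results therefore validate the
estimators and their implementation — not robustness to LD,
population stratification, informative dropout, or skewed BMI
distributions, none of which the generator produces (the rank-based
inverse-normal transform is available for the last).  One visible
consequence of exact-HWE simulation: the strict QC filter's HWE arm has
a true 5% false-positive rate per SNP, so roughly every other simulated
run drops at least one of the 12 SNPs.  This is the filter behaving as
specified; allele-count scores and per-allele regressions remain
unbiased because SNPs are independent, but the score's range (and hence
its median) shifts in such runs.

## Numerical conventions

* Logistic fits: IRLS with tolerance 1e-8, ≤ 100 iterations; apparent
  separation (non-convergence or |coefficient| > 15) is an error, never
  silent output.  OR CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{se})$.
* Rank-deficient designs raise an error naming the collinear terms.
* Age and age² enter uncentered, as specified for the reproduced
  analysis; at these magnitudes OLS on the uncentered design is
  numerically unproblematic (QR factorisation).
* Inverse-normal transform: Blom scores
  $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with average ranks on ties.
* Bootstrap AUC contrast: resample subjects within stratum; two-sided p
  as $\min\!\big(1, 2\min(\#\{d\le 0\}+1, \#\{d\ge 0\}+1)/(B+1)\big)$;
  degenerate one-class resamples are dropped.
* All randomness flows from a single seed (simulation) plus an explicit
  seed argument for the bootstrap; identical config + seed gives
  byte-identical output bundles (numeric values are written with 17
  significant digits so TSVs round-trip losslessly).
* Tie-break conventions: QC thresholds strict; the annual-change
  exclusion bounds strict (a change of exactly 2 kg/m²/y is retained);
  the score median split is "> median" vs "≤ median" — on an
  integer-valued score this is inherently asymmetric (~45/55 with the
  default panel) because a large mass sits exactly at the median.

## Known limitations

* No LD, population structure, or weighting of SNPs by effect size.
* Longitudinal trajectories are linear in time; no measurement-error
  model for self-reported activity.
* The AUC comparison is bootstrap-based and, like all such contrasts of
  overlapping models in-sample, should not be read as an independent
  validation of predictive utility.
* Heavy Monte-Carlo checks in the default test run are scaled down
  (noted test by test); the acceptance criteria themselves run at their
  stated sizes.
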