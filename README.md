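# activgps

Gene–physical-activity interaction analysis for BMI and obesity with an
unweighted genetic predisposition score.

## The scientific problem

Twelve common variants identified by GWAS (near/in *NEGR1*, *SEC16B*,
*TMEM18*, *ETV5*, *GNPDA2*, *BDNF*, *MTCH2*, *FAIM2*, *SH2B1*, *FTO*,
*MC4R*, *KCTD15*) each raise BMI by a small amount.  Summed into a
genetic predisposition score (GPS, the count of BMI-increasing alleles,
0–24), they predict BMI and obesity risk — but does lifestyle modify that
genetic effect?  `activgps` implements the full analysis used to answer
this in a large prospective cohort:

* **Score construction** — per-SNP risk-allele dosages (0/1/2), SNP QC
  (call rate > 95 %, Hardy-Weinberg equilibrium p > 0.05), and an
  unweighted allele count with mean substitution of missing genotypes
  for subjects missing ≤ 3 SNPs.
* **Physical-activity index** — four ordered levels (inactive,
  moderately inactive, moderately active, active) from occupational
  class × daily recreational activity hours.
* **Cross-sectional models** — GLM of BMI (and logistic models of
  obesity, BMI ≥ 30 vs normal 18.5 ≤ BMI < 25) on the score, adjusted
  for age, age², sex and activity:

  `BMI = β₀ + β_g·GPS + β_a·PA + γ·(GPS × PA) + β₁·age + β₂·age² + β₃·sex + ε`

  with the interaction coefficient γ measuring effect modification, plus
  activity-stratified per-allele effects, a median-split (“genetically
  susceptible”, GPS > median) contrast, and a per-SNP interaction scan
  with Bonferroni adjustment.
* **Effect conversions** — per-allele βs re-expressed as grams of body
  weight at a 1.70 m reference height (β × 1.70² × 1000), and percent
  attenuation between strata on the β or excess-odds-ratio scale.
* **Discrimination** — incremental R² of the score, and ROC AUC of the
  score + age + age² + sex obesity model by activity stratum
  (Mann–Whitney rank estimator, Hanley–McNeil CI, bootstrap AUC
  contrast).
* **Longitudinal model** — annual BMI change (Δ BMI / years) on score ×
  activity, adjusted for age, age², sex and baseline BMI.
* **Cohort simulator** — synthetic genotype/phenotype cohorts with a
  configurable score-by-activity interaction, so the whole pipeline is
  testable without individual-level cohort data (which are not public).

## Worked example

```r
library(activgps)
cfg <- run_config(simulation = sim_config(n_subjects = 20000, seed = 1),
                  n_boot = 500)
b <- run_pipeline(cfg)
b$stratified_bmi
```

```
             stratum     n   beta     se        p weight_grams
             overall 19518 0.1695 0.0135 2.98e-36          490
            inactive  5807 0.2460 0.0251 1.78e-22          711
 moderately inactive  5602 0.1682 0.0250 1.99e-11          486
   moderately active  4495 0.1389 0.0275 4.47e-07          402
              active  3614 0.0934 0.0314 2.90e-03          270
     combined active 13711 0.1389 0.0161 6.42e-18          401
```

Each row is the adjusted per-allele BMI effect within one activity
stratum of the simulated cohort (generative values 0.205 kg/m² in the
inactive group declining to 0.126 in the active group; estimates
bracket them within sampling error).  `weight_grams` is the same effect
as grams of body weight for a 1.70 m person.  The interaction itself:

```r
b$interaction_bmi_ordinal$p_interaction   # 7.2e-05  (score x activity)
attenuation_percent(b$stratified_bmi$weight_grams[2],
                    b$stratified_bmi$weight_grams[6])  # 44 (%)
for (a in b$auc) print(a)
```

```
AUC 0.627 (95% CI 0.606-0.649), 1024 cases / 1868 controls [inactive]
AUC 0.576 (95% CI 0.559-0.593), 1496 cases / 5706 controls [combined active]
```

The score discriminates obesity better among inactive subjects — the
predictive-value counterpart of the larger per-allele effect there.  The
longitudinal block (`b$longitudinal`) shows the same modification on
annual BMI change: a positive score slope in inactive subjects
(+0.0070 kg/m²/y per allele at this seed) and a negative one in active
subjects (−0.0106), interaction p = 4.7e-12 under the simulator's
default drift settings.

Printed-value utilities reproduce published derived quantities exactly:

```r
beta_to_weight(0.154, 1.70)                      # 445 (g per allele)
beta_to_weight(0.205, 1.70)                      # 592
attenuation_percent(592, 379)                    # 36 (%)
attenuation_percent(1.158, 1.095, "excess_or")   # 40 (%)
```

## Command line

```sh
Rscript inst/scripts/activgps simulate --config inst/extdata/example_config.yaml --out sim_out
Rscript inst/scripts/activgps analyze  --config inst/extdata/example_config.yaml --out report --seed 1
```

Subcommands: `simulate`, `qc`, `score`, `analyze`, `report`; flags
`--seed`, `--out`, `--skip-longitudinal`,
`--sensitivity-exclude-cvd-cancer`.  The report bundle is a directory of
TSV tables (baseline characteristics, QC report, exclusion flow,
stratified effects, interaction tests, dichotomized contrasts, per-SNP
scan, AUC, longitudinal slopes) plus a JSON run log; identical config +
seed ⇒ byte-identical bundle.

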