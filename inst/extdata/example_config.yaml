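# Example activgps pipeline configuration (simulation route).
# All thresholds shown at their defaults; delete the simulation block and
# add an inputs block (genotype/phenotype/snp_sheet paths) to analyse
# real files instead.
simulation:
  n_subjects: 20000
  seed: 1
  beta_per_allele_inactive: 0.205     # kg/m^2 per allele, inactive
  interaction_slope: -0.0263          # kg/m^2 per allele per level
  beta_activity: -0.313               # kg/m^2 per activity level
  noise_sd: 3.6
  activity_proportions: [0.302, 0.285, 0.228, 0.185]
  genotype_missing_rate: 0.04
  dropout_rate: 0.416
analyses: [cross_sectional, longitudinal, per_snp, dichotomized,
           discrimination]
height_ref: 1.70
call_rate_min: 0.95
hwe_p_min: 0.05
bmi_change_max: 2        # kg/m^2 per year
waist_change_max: 7      # cm per year
n_boot: 1000
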