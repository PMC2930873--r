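#' Simulation configuration for synthetic cohorts
#'
#' Assembles and validates every generative parameter of the cohort
#' simulator.  Defaults describe a cohort of the scale and structure the
#' analysis assumes: 20,000 adults aged 39-79, mean BMI about 26.2 kg/m^2,
#' four activity levels with proportions (0.302, 0.285, 0.228, 0.185), a
#' per-allele BMI effect of 0.205 kg/m^2 among inactive subjects declining
#' linearly by 0.0263 kg/m^2 per activity level (0.126 at the highest
#' level), a 0.313 kg/m^2 reduction per activity level, 3-4 years of
#' follow-up with mean drift +0.05 kg/m^2/y, 4% genotype missingness per
#' call, and 41.6% follow-up dropout.
#'
#' The per-allele effect at activity level L is
#' `beta_per_allele_inactive + L * interaction_slope` and must remain
#' non-negative for L in 0..3.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer RNG seed (single stream per run).
#' @param snp_specs `snp_spec` data frame with risk-allele frequencies.
#' @param intercept_bmi Baseline BMI intercept (kg/m^2).
#' @param beta_per_allele_inactive Per-allele BMI effect at activity
#'   level 0 (kg/m^2).
#' @param interaction_slope Change in the per-allele effect per activity
#'   level (kg/m^2; negative = attenuation).
#' @param beta_activity BMI change per activity level (kg/m^2).
#' @param beta_age,beta_age2,beta_sex Covariate effects on BMI (kg/m^2 per
#'   year, per year^2, and for male vs female).
#' @param noise_sd Residual BMI standard deviation (kg/m^2), > 0.
#' @param activity_proportions Four probabilities summing to 1 for levels
#'   0-3.
#' @param age_range Two-vector of age bounds in years.
#' @param sex_ratio Proportion male.
#' @param followup_years_range Two-vector, years between health checks.
#' @param annual_drift_mean,annual_drift_sd Mean and SD of per-subject
#'   annual BMI drift (kg/m^2/y).
#' @param drift_score_inactive Per-allele annual drift among inactive
#'   subjects (kg/m^2/y per allele); with `drift_interaction_slope` this
#'   reproduces the longitudinal pattern of a positive score effect on
#'   annual BMI change in inactive and a negative one in active subjects.
#' @param drift_interaction_slope Change in the per-allele drift per
#'   activity level (kg/m^2/y).
#' @param genotype_missing_rate Per-genotype-call missingness probability.
#' @param dropout_rate Probability a subject misses follow-up.
#' @param prevalence_t2d,prevalence_cvd,prevalence_cancer Prevalent-disease
#'   probabilities (T2D drives the primary exclusion; CVD/cancer feed the
#'   sensitivity exclusion).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20000L,
                       seed = 1L,
                       snp_specs = default_snp_panel(),
                       intercept_bmi = 15.5,
                       beta_per_allele_inactive = 0.205,
                       interaction_slope = -0.0263,
                       beta_activity = -0.313,
                       beta_age = 0.30,
                       beta_age2 = -0.0025,
                       beta_sex = 0.30,
                       noise_sd = 3.6,
                       activity_proportions = c(0.302, 0.285, 0.228, 0.185),
                       age_range = c(39, 79),
                       sex_ratio = 0.49,
                       followup_years_range = c(3, 4),
                       annual_drift_mean = 0.05,
                       annual_drift_sd = 0.2,
                       drift_score_inactive = 0.006,
                       drift_interaction_slope = -0.004,
                       genotype_missing_rate = 0.04,
                       dropout_rate = 0.416,
                       prevalence_t2d = 0.025,
                       prevalence_cvd = 0.055,
                       prevalence_cancer = 0.22) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (!inherits(snp_specs, "data.frame") || nrow(snp_specs) < 1L) {
    stop("snp_specs must be a non-empty snp_spec data frame")
  }
  p <- snp_specs$risk_allele_frequency
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("every risk_allele_frequency must lie strictly in (0, 1)")
  }
  if (length(activity_proportions) != 4L ||
      any(activity_proportions < 0) ||
      abs(sum(activity_proportions) - 1) > 1e-9) {
    stop("activity_proportions must be 4 non-negative values summing to 1")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  rates <- c(genotype_missing_rate, dropout_rate, prevalence_t2d,
             prevalence_cvd, prevalence_cancer, sex_ratio)
  if (any(rates < 0) || any(rates > 1)) {
    stop("all rates and proportions must lie in [0, 1]")
  }
  per_allele <- beta_per_allele_inactive + (0:3) * interaction_slope
  if (any(per_allele < 0)) {
    stop("per-allele effect must stay >= 0 across activity levels 0-3")
  }
  if (length(age_range) != 2L || age_range[1] <= 0 ||
      age_range[2] < age_range[1]) {
    stop("age_range must be increasing and positive")
  }
  if (length(followup_years_range) != 2L || followup_years_range[1] <= 0 ||
      followup_years_range[2] < followup_years_range[1]) {
    stop("followup_years_range must be increasing and positive")
  }
  cfg <- list(
    n_subjects = n_subjects, seed = seed, snp_specs = snp_specs,
    intercept_bmi = intercept_bmi,
    beta_per_allele_inactive = beta_per_allele_inactive,
    interaction_slope = interaction_slope,
    beta_activity = beta_activity,
    beta_age = beta_age, beta_age2 = beta_age2, beta_sex = beta_sex,
    noise_sd = noise_sd,
    activity_proportions = activity_proportions,
    age_range = age_range, sex_ratio = sex_ratio,
    followup_years_range = followup_years_range,
    annual_drift_mean = annual_drift_mean,
    annual_drift_sd = annual_drift_sd,
    drift_score_inactive = drift_score_inactive,
    drift_interaction_slope = drift_interaction_slope,
    genotype_missing_rate = genotype_missing_rate,
    dropout_rate = dropout_rate,
    prevalence_t2d = prevalence_t2d,
    prevalence_cvd = prevalence_cvd,
    prevalence_cancer = prevalence_cancer
  )
  class(cfg) <- "sim_config"
  cfg
}
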