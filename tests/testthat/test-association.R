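test_that("beta_to_weight reproduces the printed gram conversions", {
  expect_equal(beta_to_weight(0.154, 1.70), 445)
  expect_equal(beta_to_weight(0.205, 1.70), 592)
  expect_equal(beta_to_weight(0.126, 1.70), 364)
  expect_equal(beta_to_weight(0.131, 1.70), 379)
  expect_equal(beta_to_weight(0, 1.70), 0)
  expect_equal(beta_to_weight(-0.1, 1.70), -289)
  expect_error(beta_to_weight(0.1, 0), "> 0")
})

test_that("beta_to_weight is linear before rounding", {
  for (b in c(0.01, 0.1, 0.2, -0.15)) {
    for (a in c(2, 3, 10)) {
      expect_lte(abs(beta_to_weight(a * b) - a * b * 1.70^2 * 1000), 0.5)
    }
  }
})

test_that("attenuation_percent works on both scales", {
  expect_equal(attenuation_percent(592, 379), 36)
  expect_equal(attenuation_percent(1.158, 1.095, scale = "excess_or"), 40)
  expect_equal(attenuation_percent(0.2, 0.2), 0)
  expect_error(attenuation_percent(0, 0.1), "nonzero")
  expect_error(attenuation_percent(0.99, 0.9, scale = "excess_or"),
               "undefined")
})

test_that("inverse_normal applies Blom scores with average-rank ties", {
  x <- c(3, 10, 200, -5, 7)
  out <- inverse_normal(x)
  probs <- (rank(x) - 3 / 8) / (5 + 1 / 4)
  expect_equal(out, stats::qnorm(probs))
  expect_equal(sort(round(probs[order(x)], 4)),
               c(0.1190, 0.3095, 0.5, 0.6905, 0.8810))
  # middle of three distinct values maps to zero
  expect_equal(inverse_normal(c(1, 5, 9))[2], 0)
  # invariant under strictly monotone transforms
  expect_equal(inverse_normal(exp(x)), inverse_normal(x))
  expect_error(inverse_normal(rep(1, 4)), "identical")
  expect_error(inverse_normal(3), "at least 2")
})

test_that("score main effect recovers the generative per-allele beta", {
  cfg <- quiet_config(20000, seed = 201,
                      beta_per_allele_inactive = 0.154,
                      interaction_slope = 0)
  d <- sim_model_data(cfg)$data
  fit <- score_main_effect(d, "bmi")
  row <- coef_row(fit, "score")
  expect_lt(abs(row$estimate - 0.154), 3 * row$se)
})

test_that("logistic outcomes are restricted to their defining categories", {
  d <- sim_model_data(quiet_config(4000, seed = 11))$data
  fit <- score_main_effect(d, "obesity")
  expect_equal(fit$n_used, sum(d$bmi_cat %in% c("obese", "normal")))
  fit_ow <- score_main_effect(d, "overweight")
  expect_equal(fit_ow$n_used,
               sum(d$bmi_cat %in% c("obese", "overweight_only", "normal")))
  expect_error(score_main_effect(d, "waist"), "outcome")
})

test_that("binary interaction coding equals merging the active levels", {
  d <- sim_model_data(quiet_config(5000, seed = 31))$data
  it_bin <- interaction_test(d, "bmi", coding = "binary")
  d2 <- d
  d2$activity <- d$active_any
  it_merged <- interaction_test(d2, "bmi", coding = "ordinal")
  expect_equal(it_bin$estimate, it_merged$estimate, tolerance = 1e-10)
  expect_equal(it_bin$p_interaction, it_merged$p_interaction,
               tolerance = 1e-10)
})

test_that("interaction with a single activity level is an error", {
  d <- sim_model_data(quiet_config(2000, seed = 7))$data
  d$activity <- 0L
  d$active_any <- 0L
  expect_error(interaction_test(d, "bmi"), "single activity level")
})

test_that("stratified effects recover the generative gradient", {
  d <- sim_model_data(quiet_config(20000, seed = 51))$data
  eff <- stratified_effects(d, "bmi")
  expect_identical(eff$stratum,
                   c("overall", "inactive", "moderately inactive",
                     "moderately active", "active", "combined active"))
  gen <- c(NA, 0.205, 0.205 - 0.0263, 0.205 - 2 * 0.0263,
           0.205 - 3 * 0.0263, NA)
  for (i in c(2:5)) {
    expect_lt(abs(eff$beta[i] - gen[i]), 3 * eff$se[i],
              label = eff$stratum[i])
  }
  expect_equal(eff$weight_grams, beta_to_weight(eff$beta))
  # inactive-stratum beta consistent with the interaction decomposition
  it <- interaction_test(d, "bmi")
  main_at_0 <- coef_row(it$model, "score")$estimate
  expect_lt(abs(eff$beta[2] - main_at_0),
            3 * sqrt(eff$se[2]^2 + coef_row(it$model, "score")$se^2))
})

test_that("strata are homogeneous when no interaction is simulated", {
  d <- sim_model_data(quiet_config(15000, seed = 61,
                                   interaction_slope = 0))$data
  eff <- stratified_effects(d, "bmi")
  lv <- eff[eff$stratum %in% c("inactive", "moderately inactive",
                               "moderately active", "active"), ]
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lt(abs(lv$beta[i] - lv$beta[j]),
                4 * sqrt(lv$se[i]^2 + lv$se[j]^2))
    }
  }
})

test_that("stratified obesity effects carry ORs with valid CIs", {
  d <- sim_model_data(quiet_config(15000, seed = 71))$data
  eff <- stratified_effects(d, "obesity")
  expect_true(all(eff$or_low <= eff$or & eff$or <= eff$or_high))
  expect_true(all(eff$n_cases + eff$n_controls == eff$n))
  # inactive per-allele OR should exceed the active one on average;
  # at least require both above 1 under the default effect sizes
  expect_gt(eff$or[eff$stratum == "inactive"], 1)
})

test_that("dichotomized contrast groups and nulls behave", {
  d <- sim_model_data(quiet_config(20000, seed = 81))$data
  dc <- dichotomized_contrast(d, "bmi")
  frac_high <- dc$n_high / (dc$n_high + dc$n_low)
  expect_true(all(abs(frac_high - 0.5) < 0.1))
  expect_true(all(dc$beta > 0))  # high-score group heavier by design

  # identical BMI distributions in both groups -> contrast near zero
  set.seed(99)
  null_d <- data.frame(score = stats::rnorm(8000, 11, 2),
                       bmi = stats::rnorm(8000, 26, 3.5),
                       age = stats::runif(8000, 40, 78),
                       sex01 = stats::rbinom(8000, 1, 0.5),
                       activity = sample(0:3, 8000, replace = TRUE))
  null_d$age2 <- null_d$age^2
  dc0 <- dichotomized_contrast(null_d, "bmi")
  expect_true(all(abs(dc0$beta / dc0$se) < 4))
  # with a continuous symmetric score the median split is near 50/50
  frac0 <- dc0$n_high / (dc0$n_high + dc0$n_low)
  expect_true(all(abs(frac0 - 0.5) < 0.05))

  expect_error(dichotomized_contrast(d, "bmi",
                                     threshold = max(d$score) + 1),
               "degenerate")
})

test_that("per-SNP scan applies Bonferroni and skips monomorphic SNPs", {
  sm <- sim_model_data(quiet_config(4000, seed = 91))
  scan <- per_snp_interactions(sm$panel, sm$data, "bmi")
  expect_equal(nrow(scan), 12L)
  expect_equal(scan$p_bonferroni, pmin(1, scan$p * 12))

  dos <- sm$panel$dosage
  dos[, 1] <- 1L  # monomorphic
  panel2 <- genotype_panel(dos, sm$panel$subject_ids)
  expect_warning(scan2 <- per_snp_interactions(panel2, sm$data, "bmi"),
                 "monomorphic")
  expect_equal(nrow(scan2), 11L)
  expect_equal(scan2$p_bonferroni, pmin(1, scan2$p * 11))
})

test_that("longitudinal slopes are exact in the noiseless limit", {
  cfg <- quiet_config(4000, seed = 101,
                      annual_drift_sd = 1e-12,
                      drift_score_inactive = 0.01,
                      drift_interaction_slope = -0.005)
  d <- sim_model_data(cfg)$data
  res <- longitudinal_interaction(d)
  gen <- 0.01 - 0.005 * res$slopes$level
  expect_equal(res$slopes$slope, gen, tolerance = 1e-6)
  expect_equal(res$interaction$estimate, -0.005, tolerance = 1e-6)
})

test_that("score is unrelated to annual change when drift ignores it", {
  cfg <- quiet_config(12000, seed = 111,
                      drift_score_inactive = 0,
                      drift_interaction_slope = 0)
  d <- sim_model_data(cfg)$data
  res <- longitudinal_interaction(d)
  row <- coef_row(res$overall, "score")
  expect_lt(abs(row$estimate / row$se), 4)
})
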