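#' Assemble the modelling frame
#'
#' Joins predisposition scores onto the post-exclusion analysis set and
#' adds the derived model columns: `score`, `activity` (ordinal 0-3),
#' `age2`, `sex01` (F = 0, M = 1), `bmi` (baseline), `bmi_cat`, the
#' obesity/overweight contrast indicators (NA outside their defining
#' categories), and the combined-active indicator `active_any`.
#' Subjects without a defined score (more than 3 missing genotypes) are
#' dropped.
#'
#' @param analysis_set Output of [apply_exclusions()] (`analysis_set`).
#' @param scores Output of [compute_scores()].
#' @return A data frame ready for the model-fitting functions.
#' @export
prepare_model_data <- function(analysis_set, scores) {
  sc <- scores[scores$complete, c("subject_id", "score")]
  d <- merge(analysis_set, sc, by = "subject_id")
  d$activity <- d$activity_level
  d$age2 <- d$age^2
  d$sex01 <- as.integer(d$sex == "M")
  d$bmi <- d$bmi_baseline
  d$bmi_cat <- bmi_category(d$bmi)
  d$obese <- ifelse(d$bmi_cat == "obese", 1L,
                    ifelse(d$bmi_cat == "normal", 0L, NA_integer_))
  d$overweight <- ifelse(d$bmi_cat %in% c("obese", "overweight_only"), 1L,
                         ifelse(d$bmi_cat == "normal", 0L, NA_integer_))
  d$active_any <- as.integer(d$activity >= 1L)
  d
}

base_covariates <- c("age", "age2", "sex01")

outcome_column <- function(outcome) {
  switch(outcome,
         bmi = "bmi",
         obesity = "obese",
         overweight = "overweight",
         stop("outcome must be one of bmi, obesity, overweight"))
}

fit_for_outcome <- function(data, outcome, terms) {
  col <- outcome_column(outcome)
  if (outcome == "bmi") fit_linear(data, col, terms)
  else fit_logistic(data, col, terms)
}

#' Adjusted main effect of the predisposition score
#'
#' Per-allele association of the score with BMI (linear) or with obesity
#' or overweight risk (logistic, restricted by construction to the two
#' defining BMI categories), adjusted for age, age^2, sex and physical
#' activity (ordinal).
#'
#' @param data Frame from [prepare_model_data()].
#' @param outcome One of `"bmi"`, `"obesity"`, `"overweight"`.
#' @return A `model_result`.
#' @export
score_main_effect <- function(data, outcome = "bmi") {
  fit_for_outcome(data, outcome,
                  c("score", base_covariates, "activity"))
}

#' Score-by-activity interaction test
#'
#' Adds a score x activity product term to the adjusted main-effects
#' model; the reported interaction p comes from that model with both main
#' effects retained.  Activity enters either as the ordinal 0-3 level or
#' as the binary combined-active (levels 1-3) vs inactive contrast.
#'
#' @inheritParams score_main_effect
#' @param coding `"ordinal"` (default) or `"binary"`.
#' @param score_var Model column to interact with activity (the score by
#'   default; a SNP dosage column for per-SNP scans).
#' @return List of class `interaction_result`: `estimate`, `se`,
#'   `p_interaction`, `coding`, `model`.
#' @export
interaction_test <- function(data, outcome = "bmi",
                             coding = c("ordinal", "binary"),
                             score_var = "score") {
  coding <- match.arg(coding)
  act <- if (coding == "ordinal") "activity" else "active_any"
  if (length(unique(stats::na.omit(data[[act]]))) < 2L) {
    stop("interaction undefined: a single activity level in the data")
  }
  terms <- c(score_var, act, base_covariates,
             paste0(score_var, ":", act))
  model <- fit_for_outcome(data, outcome, terms)
  row <- coef_row(model, paste0(score_var, ":", act))
  structure(list(estimate = row$estimate, se = row$se,
                 p_interaction = row$p, coding = coding, model = model),
            class = "interaction_result")
}

#' Per-allele effects stratified by activity level
#'
#' Refits the adjusted per-allele model within each activity level, in
#' the combined-active stratum (levels 1-3) and overall.  Within a
#' stratum the activity covariate is dropped; overall it is retained.
#' Linear betas carry their gram equivalent at the reference height.
#'
#' @inheritParams score_main_effect
#' @param height_ref Reference height in metres for the gram conversion.
#' @return Data frame with one row per stratum: `stratum`, `n`, and for
#'   linear outcomes `beta`, `se`, `p`, `weight_grams`; for logistic
#'   outcomes `or`, `or_low`, `or_high`, `p`, plus `n_controls`/`n_cases`.
#' @export
stratified_effects <- function(data, outcome = "bmi", height_ref = 1.70) {
  strata <- list(
    overall = rep(TRUE, nrow(data)),
    inactive = data$activity == 0L,
    `moderately inactive` = data$activity == 1L,
    `moderately active` = data$activity == 2L,
    active = data$activity == 3L,
    `combined active` = data$activity >= 1L
  )
  rows <- lapply(names(strata), function(nm) {
    sub <- data[strata[[nm]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    terms <- if (nm == "overall") c("score", base_covariates, "activity")
             else c("score", base_covariates)
    model <- fit_for_outcome(sub, outcome, terms)
    row <- coef_row(model, "score")
    if (outcome == "bmi") {
      data.frame(stratum = nm, n = model$n_used,
                 beta = row$estimate, se = row$se, p = row$p,
                 weight_grams = beta_to_weight(row$estimate, height_ref),
                 stringsAsFactors = FALSE)
    } else {
      y <- sub[[outcome_column(outcome)]]
      data.frame(stratum = nm, n = model$n_used,
                 n_controls = sum(y == 0, na.rm = TRUE),
                 n_cases = sum(y == 1, na.rm = TRUE),
                 or = row$or, or_low = row$or_low, or_high = row$or_high,
                 p = row$p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a per-allele BMI effect to grams of body weight
#'
#' `beta * height^2 * 1000`, rounded half away from zero to whole grams:
#' weight = BMI x height^2, so a BMI difference maps to kilograms via the
#' squared reference height.
#'
#' @param beta BMI effect (kg/m^2).
#' @param height Reference height in metres (> 0), default 1.70.
#' @return Grams (integer-valued numeric).
#' @export
beta_to_weight <- function(beta, height = 1.70) {
  if (any(height <= 0)) stop("height must be > 0")
  round_half_away(beta * height^2 * 1000)
}

#' Percent attenuation of a genetic effect between strata
#'
#' Beta scale: `(effect_inactive - effect_active) / effect_inactive x
#' 100`.  Excess-odds-ratio scale: the same contrast on `OR - 1`.
#' Rounded to whole percent.
#'
#' @param effect_inactive,effect_active Effects in the reference
#'   (inactive) and comparison (active) strata: betas or gram equivalents
#'   on the beta scale, odds ratios on the excess-OR scale.
#' @param scale `"beta"` or `"excess_or"`.
#' @return Integer percent attenuation.
#' @export
attenuation_percent <- function(effect_inactive, effect_active,
                                scale = c("beta", "excess_or")) {
  scale <- match.arg(scale)
  if (scale == "beta") {
    if (effect_inactive == 0) stop("reference effect must be nonzero")
    pct <- (effect_inactive - effect_active) / effect_inactive * 100
  } else {
    if (effect_inactive <= 1) {
      stop("excess-OR attenuation undefined for OR_inactive <= 1")
    }
    pct <- ((effect_inactive - 1) - (effect_active - 1)) /
      (effect_inactive - 1) * 100
  }
  round_half_away(pct)
}

#' High- vs low-susceptibility contrast at the score median
#'
#' Dichotomizes the score at a threshold (by default the median over the
#' full frame) into genetically susceptible (score > threshold) and
#' nonsusceptible groups, and contrasts them on BMI (linear) or obesity
#' odds (logistic) within the inactive and combined-active strata,
#' adjusted for age, age^2 and sex.
#'
#' @inheritParams stratified_effects
#' @param threshold Score cut; default `median(data$score)`.
#' @return Data frame, one row per stratum, with group sizes and the
#'   contrast estimate (beta + grams, or OR + CI).
#' @export
dichotomized_contrast <- function(data, outcome = "bmi", threshold = NULL,
                                  height_ref = 1.70) {
  if (is.null(threshold)) threshold <- stats::median(data$score)
  data$high_score <- as.integer(data$score > threshold)
  if (length(unique(data$high_score)) < 2L) {
    stop("degenerate threshold: all subjects fall in one group")
  }
  strata <- list(inactive = data$activity == 0L,
                 `combined active` = data$activity >= 1L)
  rows <- lapply(names(strata), function(nm) {
    sub <- data[strata[[nm]], , drop = FALSE]
    model <- fit_for_outcome(sub, outcome,
                             c("high_score", base_covariates))
    row <- coef_row(model, "high_score")
    base <- data.frame(stratum = nm, threshold = threshold,
                       n_low = sum(sub$high_score == 0),
                       n_high = sum(sub$high_score == 1),
                       stringsAsFactors = FALSE)
    if (outcome == "bmi") {
      cbind(base, data.frame(
        beta = row$estimate, se = row$se, p = row$p,
        weight_grams = beta_to_weight(row$estimate, height_ref)))
    } else {
      cbind(base, data.frame(
        or = row$or, or_low = row$or_low, or_high = row$or_high,
        p = row$p))
    }
  })
  do.call(rbind, rows)
}

#' Per-SNP dosage-by-activity interaction scan
#'
#' Tests each SNP's dosage x activity interaction on the chosen outcome
#' (complete cases per SNP), with Bonferroni adjustment over the SNPs
#' actually tested.  Monomorphic SNPs are skipped with a warning.
#'
#' @param panel QC-passed `genotype_panel`.
#' @param data Frame from [prepare_model_data()].
#' @param outcome One of `"bmi"`, `"obesity"`, `"overweight"`.
#' @param coding Activity coding, as in [interaction_test()].
#' @return Data frame: `snp_id`, `estimate`, `se`, `p`, `p_bonferroni`.
#' @export
per_snp_interactions <- function(panel, data, outcome = "bmi",
                                 coding = "ordinal") {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- match(data$subject_id, panel$subject_ids)
  if (anyNA(idx)) stop("subjects in data missing from the genotype panel")
  rows <- lapply(panel$snp_ids, function(snp) {
    d <- data
    d$dosage <- panel$dosage[idx, snp]
    if (length(unique(stats::na.omit(d$dosage))) < 2L) {
      warning("skipping monomorphic SNP ", snp)
      return(NULL)
    }
    it <- interaction_test(d, outcome, coding, score_var = "dosage")
    data.frame(snp_id = snp, estimate = it$estimate, se = it$se,
               p = it$p_interaction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no testable SNPs in panel")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Rank-based inverse normal transform
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving their
#' average rank.  Invariant under any strictly monotone transform of the
#' input.
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @return Transformed values (mean approximately 0).
#' @export
inverse_normal <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (length(unique(values)) < 2L) stop("all values identical")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Longitudinal score-by-activity interaction on annual BMI change
#'
#' Restricts to subjects with follow-up, models the annual BMI change on
#' score, activity and their product, adjusted for age, age^2, sex and
#' baseline BMI, and reports per-stratum score slopes from the same
#' adjusted model refitted within each activity level.
#'
#' @inheritParams score_main_effect
#' @param coding Activity coding for the interaction term.
#' @return List of class `longitudinal_result`: `interaction` (an
#'   `interaction_result`), `overall` (score `model_result` without the
#'   interaction), `slopes` (data frame stratum/n/slope/se/p).
#' @export
longitudinal_interaction <- function(data, coding = "ordinal") {
  d <- data[!is.na(data$annual_bmi_change), , drop = FALSE]
  if (!nrow(d)) stop("no follow-up data available")
  covars <- c(base_covariates, "bmi")
  act <- if (coding == "ordinal") "activity" else "active_any"
  model <- fit_linear(d, "annual_bmi_change",
                      c("score", act, covars,
                        paste0("score:", act)))
  row <- coef_row(model, paste0("score:", act))
  inter <- structure(list(estimate = row$estimate, se = row$se,
                          p_interaction = row$p, coding = coding,
                          model = model),
                     class = "interaction_result")
  overall <- fit_linear(d, "annual_bmi_change",
                        c("score", act, covars))
  slopes <- do.call(rbind, lapply(0:3, function(lv) {
    sub <- d[d$activity == lv, , drop = FALSE]
    if (nrow(sub) < 10L) return(NULL)
    m <- fit_linear(sub, "annual_bmi_change", c("score", covars))
    r <- coef_row(m, "score")
    data.frame(stratum = unname(activity_labels()[as.character(lv)]),
               level = lv, n = m$n_used, slope = r$estimate,
               se = r$se, p = r$p, stringsAsFactors = FALSE)
  }))
  structure(list(interaction = inter, overall = overall, slopes = slopes),
            class = "longitudinal_result")
}
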