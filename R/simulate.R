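#' Simulate genotypes for a synthetic cohort
#'
#' Draws each SNP's risk-allele dosage Binomial(2, p_j) independently
#' across subjects (Hardy-Weinberg proportions by construction), then
#' injects missingness uniformly at random at the configured per-call
#' rate.  Seeds the single RNG stream from `config$seed`, so the same
#' config always yields the same panel.  The complete pre-missingness
#' matrix is kept as attribute `true_dosage` for phenotype generation.
#'
#' @param config A `sim_config`.
#' @return A `genotype_panel`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  specs <- config$snp_specs
  m <- nrow(specs)
  dosage <- matrix(NA_integer_, n, m,
                   dimnames = list(NULL, specs$snp_id))
  for (j in seq_len(m)) {
    dosage[, j] <- stats::rbinom(n, 2L, specs$risk_allele_frequency[j])
  }
  true_dosage <- dosage
  if (config$genotype_missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < config$genotype_missing_rate, n, m)
    dosage[drop] <- NA_integer_
  }
  panel <- genotype_panel(dosage, sprintf("s%05d", seq_len(n)))
  attr(panel, "true_dosage") <- true_dosage
  panel
}

# Draw an (occupation, hours) cell uniformly among those consistent with
# each target activity level, so classify_activity() recovers the level
# exactly.  Cells follow the four-level occupational/recreational index.
backfill_activity_inputs <- function(level) {
  n <- length(level)
  occupation <- character(n)
  hours <- numeric(n)
  u_cell <- stats::runif(n)       # which cell within the level
  u_hours <- stats::runif(n)      # position within the cell's interval
  for (lv in 0:3) {
    idx <- which(level == lv)
    if (!length(idx)) next
    k <- switch(as.character(lv), "0" = 1L, "1" = 2L, "2" = 3L, "3" = 4L)
    cell <- ceiling(u_cell[idx] * k)
    occ <- character(length(idx))
    hrs <- numeric(length(idx))
    u <- u_hours[idx]
    if (lv == 0L) {
      occ[] <- "sedentary"; hrs[] <- 0
    } else if (lv == 1L) {
      occ[cell == 1L] <- "sedentary"
      hrs[cell == 1L] <- 0.01 + u[cell == 1L] * 0.48   # (0, 0.5)
      occ[cell == 2L] <- "standing"
      hrs[cell == 2L] <- 0
    } else if (lv == 2L) {
      occ[cell == 1L] <- "sedentary"
      hrs[cell == 1L] <- 0.5 + u[cell == 1L] * 0.5     # [0.5, 1]
      occ[cell == 2L] <- "standing"
      hrs[cell == 2L] <- 0.01 + u[cell == 2L] * 0.48   # (0, 0.5)
      occ[cell == 3L] <- "physical"
      hrs[cell == 3L] <- 0
    } else {
      occ[cell == 1L] <- "sedentary"
      hrs[cell == 1L] <- 1.01 + u[cell == 1L] * 2      # > 1
      occ[cell == 2L] <- "standing"
      hrs[cell == 2L] <- 0.5 + u[cell == 2L] * 1.5     # >= 0.5
      occ[cell == 3L] <- "physical"
      hrs[cell == 3L] <- 0.25 + u[cell == 3L] * 1.75   # > 0
      occ[cell == 4L] <- "heavy"
      hrs[cell == 4L] <- u[cell == 4L] * 2             # any
    }
    occupation[idx] <- occ
    hours[idx] <- hrs
  }
  data.frame(occupation = occupation,
             recreation_hours_per_day = hours,
             stringsAsFactors = FALSE)
}

#' Simulate phenotypes for a genotype panel
#'
#' Generates baseline and follow-up phenotypes under an additive genetic
#' model whose per-allele BMI effect declines linearly with activity
#' level:
#' `BMI = intercept + g * (beta_inactive + A * slope) + beta_activity * A
#'  + beta_age * age + beta_age2 * age^2 + beta_sex * male + N(0, sd^2)`,
#' where `g` is the subject's total risk-allele count.  Occupation and
#' recreational hours are back-filled consistently with the generative
#' activity level.  Follow-up BMI adds `years * drift`, with the drift
#' containing an optional score-by-activity component; waist is affine in
#' BMI plus noise (it exists only to exercise the waist exclusion
#' filter).  Continues the RNG stream opened by [simulate_genotypes()].
#'
#' @param config A `sim_config`.
#' @param panel The matching `genotype_panel`.
#' @return A data frame of subject records (one row per subject) with a
#'   `true_activity` column carrying the generative level.
#' @export
simulate_phenotypes <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  n <- config$n_subjects
  if (length(panel$subject_ids) != n) {
    stop("panel subject count does not match config$n_subjects")
  }
  g_mat <- attr(panel, "true_dosage")
  if (is.null(g_mat)) {
    # externally built panel: fall back to mean-filled observed dosages
    g_mat <- panel$dosage
    means <- colMeans(g_mat, na.rm = TRUE)
    for (j in seq_len(ncol(g_mat))) {
      g_mat[is.na(g_mat[, j]), j] <- means[j]
    }
  }
  g <- rowSums(g_mat)

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "M", "F")
  activity <- sample(0:3, n, replace = TRUE,
                     prob = config$activity_proportions)
  per_allele <- config$beta_per_allele_inactive +
    activity * config$interaction_slope
  bmi0 <- config$intercept_bmi + g * per_allele +
    config$beta_activity * activity +
    config$beta_age * age + config$beta_age2 * age^2 +
    config$beta_sex * (sex == "M") +
    stats::rnorm(n, 0, config$noise_sd)

  years <- stats::runif(n, config$followup_years_range[1],
                        config$followup_years_range[2])
  drift <- stats::rnorm(n, config$annual_drift_mean,
                        config$annual_drift_sd) +
    g * (config$drift_score_inactive +
           activity * config$drift_interaction_slope)
  bmi1 <- bmi0 + years * drift
  waist0 <- 24 + 2.5 * bmi0 + stats::rnorm(n, 0, 3)
  waist1 <- 24 + 2.5 * bmi1 + stats::rnorm(n, 0, 3)

  dropout <- stats::runif(n) < config$dropout_rate
  bmi1[dropout] <- NA_real_
  waist1[dropout] <- NA_real_
  years[dropout] <- NA_real_

  backfill <- backfill_activity_inputs(activity)

  data.frame(
    subject_id = panel$subject_ids,
    sex = sex,
    age = age,
    bmi_baseline = bmi0,
    bmi_followup = bmi1,
    waist_baseline = waist0,
    waist_followup = waist1,
    followup_years = years,
    occupation = backfill$occupation,
    recreation_hours_per_day = backfill$recreation_hours_per_day,
    prevalent_t2d = as.integer(stats::runif(n) < config$prevalence_t2d),
    prevalent_cvd = as.integer(stats::runif(n) < config$prevalence_cvd),
    prevalent_cancer = as.integer(stats::runif(n) < config$prevalence_cancer),
    true_activity = activity,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort (genotypes + phenotypes)
#'
#' @param config A `sim_config`.
#' @return A list with elements `panel` and `records`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_genotypes(config)
  records <- simulate_phenotypes(config, panel)
  list(panel = panel, records = records)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort to genotype and phenotype TSV files
#'
#' Genotype TSV: `subject_id` then one column per SNP, cells in
#' \{0, 1, 2, NA\}.  Phenotype TSV: one row per subject with the standard
#' columns.  Numeric values are written with 17 significant digits so the
#' files round-trip losslessly through [read_genotype_table()] and
#' [read_phenotype_table()].
#'
#' @param panel A `genotype_panel`.
#' @param records The matching subject-record data frame.
#' @param genotype_path,phenotype_path Output file paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(panel, records, genotype_path, phenotype_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!identical(panel$subject_ids, records$subject_id)) {
    stop("panel and records must list the same subjects in the same order")
  }
  gt <- data.frame(subject_id = panel$subject_ids,
                   panel$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(gt, genotype_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write genotype file: ",
                              conditionMessage(e)))

  ph <- records
  ph$true_activity <- NULL
  num_cols <- c("age", "bmi_baseline", "bmi_followup", "waist_baseline",
                "waist_followup", "followup_years",
                "recreation_hours_per_day")
  for (cl in num_cols) ph[[cl]] <- fmt_num(ph[[cl]])
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(genotype = genotype_path, phenotype = phenotype_path))
}

#' Export a genotype panel as a minimal GT-only VCF
#'
#' One record per SNP on a placeholder contig; REF is the other allele and
#' ALT the risk allele, genotypes unphased (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param panel A `genotype_panel`.
#' @param specs `snp_spec` data frame covering the panel's SNPs.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, specs, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  miss <- setdiff(panel$snp_ids, specs$snp_id)
  if (length(miss)) {
    stop("snp_specs missing definitions for: ", paste(miss, collapse = ", "))
  }
  specs <- specs[match(panel$snp_ids, specs$snp_id), ]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", panel$subject_ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(panel$snp_ids), function(j) {
    d <- panel$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c("1", as.character(j * 1000L), panel$snp_ids[j],
            specs$other_allele[j], specs$risk_allele[j],
            ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
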