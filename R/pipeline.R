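#' Build a pipeline run configuration
#'
#' Exactly one of `simulation` and `inputs` must be supplied: either the
#' cohort is simulated (a [sim_config()] or a list of its arguments) or
#' read from files (`inputs` is a list with `genotype`, `phenotype` and
#' `snp_sheet` paths; a `.vcf` genotype path is read as VCF).
#'
#' @param simulation A `sim_config`, or a list of arguments for one.
#' @param inputs List of input paths (genotype, phenotype, snp_sheet).
#' @param out_dir Output directory for the report bundle (NULL = do not
#'   write files).
#' @param seed Integer seed; overrides the simulation block's seed and
#'   seeds the bootstrap.
#' @param height_ref Reference height (m) for gram conversions.
#' @param analyses Character vector of analysis switches, a subset of
#'   `c("cross_sectional", "longitudinal", "per_snp", "dichotomized",
#'   "discrimination")`.
#' @param sensitivity_cvd_cancer Also run the CVD/cancer sensitivity
#'   exclusion.
#' @param call_rate_min,hwe_p_min SNP QC thresholds (strict).
#' @param bmi_change_max,waist_change_max Annual-change exclusion bounds.
#' @param score_threshold Score dichotomization cut; NULL = sample median.
#' @param n_boot Bootstrap replicates for the AUC comparison.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, inputs = NULL, out_dir = NULL,
                       seed = NULL, height_ref = 1.70,
                       analyses = c("cross_sectional", "longitudinal",
                                    "per_snp", "dichotomized",
                                    "discrimination"),
                       sensitivity_cvd_cancer = FALSE,
                       call_rate_min = 0.95, hwe_p_min = 0.05,
                       bmi_change_max = 2, waist_change_max = 7,
                       score_threshold = NULL, n_boot = 1000L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of 'simulation' and 'inputs' must be given")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!is.null(simulation)) simulation$seed <- seed
  } else {
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  }
  if (!is.null(inputs)) {
    need <- c("genotype", "phenotype", "snp_sheet")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("inputs must name: ", paste(miss, collapse = ", "))
    }
  }
  known <- c("cross_sectional", "longitudinal", "per_snp",
             "dichotomized", "discrimination")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  structure(list(simulation = simulation, inputs = inputs,
                 out_dir = out_dir, seed = seed, height_ref = height_ref,
                 analyses = analyses,
                 sensitivity_cvd_cancer = sensitivity_cvd_cancer,
                 call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 bmi_change_max = bmi_change_max,
                 waist_change_max = waist_change_max,
                 score_threshold = score_threshold,
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments, with `simulation` a
#' mapping of [sim_config()] arguments (the `snp_specs` entry, if given,
#' is a list of snp_id/risk_allele/other_allele/risk_allele_frequency
#' mappings).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation) && !is.null(y$simulation$snp_specs)) {
    specs <- do.call(rbind, lapply(y$simulation$snp_specs, function(s) {
      snp_spec(s$snp_id, s$risk_allele, s$other_allele,
               s$risk_allele_frequency %||% NA_real_)
    }))
    class(specs) <- c("snp_spec", "data.frame")
    y$simulation$snp_specs <- specs
  }
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_panel <- function(panel, subject_ids) {
  idx <- match(subject_ids, panel$subject_ids)
  if (anyNA(idx)) stop("subjects missing from genotype panel")
  genotype_panel(panel$dosage[idx, , drop = FALSE], subject_ids)
}

#' Run the full analysis pipeline
#'
#' Sequences simulate/read -> SNP QC -> exclusions -> score (substitution
#' means from the analysis cohort) -> activity derivation -> adjusted
#' models, interaction tests, stratified and dichotomized effects,
#' per-SNP scan, discrimination, and the longitudinal model; renders the
#' baseline characteristics table and the exclusion flow.  With
#' `config$out_dir` set, writes every table as TSV plus a JSON run log;
#' identical config and seed give a byte-identical bundle.
#'
#' @param config A `run_config`.
#' @return The report bundle (named list), invisibly when files are
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    panel <- cohort$panel
    records <- cohort$records
    snp_specs <- config$simulation$snp_specs
  } else {
    snp_specs <- read_snp_sheet(config$inputs$snp_sheet)
    panel <- if (grepl("\\.vcf$", config$inputs$genotype)) {
      read_vcf(config$inputs$genotype, snp_specs)
    } else {
      read_genotype_table(config$inputs$genotype, snp_specs)
    }
    records <- read_phenotype_table(config$inputs$phenotype)
  }
  n_input <- nrow(records)

  qc <- qc_filter(panel, config$call_rate_min, config$hwe_p_min)
  excl <- apply_exclusions(records,
                           sensitivity_cvd_cancer =
                             config$sensitivity_cvd_cancer,
                           bmi_change_max = config$bmi_change_max,
                           waist_change_max = config$waist_change_max)
  analysis_set <- excl$analysis_set
  panel_a <- subset_panel(qc$panel, analysis_set$subject_id)
  scores <- compute_scores(panel_a)
  data <- prepare_model_data(analysis_set, scores)

  bundle <- list(
    qc_report = qc$qc_report,
    exclusion_report = excl$exclusion_report,
    scores = scores,
    model_data = data,
    baseline_table = render_baseline_table(data)
  )

  has <- function(a) a %in% config$analyses
  if (has("cross_sectional")) {
    bundle$main_effect_bmi <- score_main_effect(data, "bmi")
    bundle$main_effect_obesity <- score_main_effect(data, "obesity")
    bundle$interaction_bmi_ordinal <- interaction_test(data, "bmi",
                                                       "ordinal")
    bundle$interaction_bmi_binary <- interaction_test(data, "bmi",
                                                      "binary")
    bundle$interaction_obesity_ordinal <-
      interaction_test(data, "obesity", "ordinal")
    bundle$stratified_bmi <- stratified_effects(data, "bmi",
                                                config$height_ref)
    bundle$stratified_obesity <- stratified_effects(data, "obesity",
                                                    config$height_ref)
  }
  if (has("dichotomized")) {
    bundle$dichotomized_bmi <- dichotomized_contrast(
      data, "bmi", config$score_threshold, config$height_ref)
    bundle$dichotomized_obesity <- dichotomized_contrast(
      data, "obesity", config$score_threshold, config$height_ref)
  }
  if (has("per_snp")) {
    bundle$per_snp_bmi <- per_snp_interactions(panel_a, data, "bmi")
  }
  if (has("discrimination")) {
    bundle$auc <- auc_by_stratum(data)
    bundle$incremental_r2 <- data.frame(
      stratum = c("inactive", "active"),
      incremental_r2 = c(incremental_r2(data[data$activity == 0L, ]),
                         incremental_r2(data[data$activity == 3L, ])),
      stringsAsFactors = FALSE)
    bundle$auc_comparison <- with(bundle, {
      inact <- data[data$activity == 0L & !is.na(data$obese), ]
      act <- data[data$activity >= 1L & !is.na(data$obese), ]
      pa <- stats::fitted(fit_logistic(inact, "obese",
                                       c("score", base_covariates))$fit)
      pb <- stats::fitted(fit_logistic(act, "obese",
                                       c("score", base_covariates))$fit)
      compare_auc(pa, inact$obese, pb, act$obese,
                  n_boot = config$n_boot, seed = config$seed)
    })
  }
  if (has("longitudinal") && any(!is.na(data$annual_bmi_change))) {
    bundle$longitudinal <- longitudinal_interaction(data)
  }

  bundle$run_log <- list(
    package = "activgps",
    version = as.character(utils::packageVersion("activgps")),
    seed = config$seed,
    n_input = n_input,
    n_analysis = nrow(analysis_set),
    n_scored = sum(scores$complete),
    thresholds = list(call_rate_min = config$call_rate_min,
                      hwe_p_min = config$hwe_p_min,
                      bmi_change_max = config$bmi_change_max,
                      waist_change_max = config$waist_change_max,
                      height_ref = config$height_ref,
                      score_threshold = config$score_threshold %||%
                        stats::median(data$score)),
    analyses = config$analyses
  )

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

auc_to_df <- function(auc_list) {
  do.call(rbind, lapply(auc_list, function(a) {
    data.frame(stratum = a$stratum, auc = a$auc, ci_low = a$ci_low,
               ci_high = a$ci_high, n_cases = a$n_cases,
               n_controls = a$n_controls, stringsAsFactors = FALSE)
  }))
}

interactions_to_df <- function(bundle) {
  keys <- grep("^interaction_", names(bundle), value = TRUE)
  do.call(rbind, lapply(keys, function(k) {
    it <- bundle[[k]]
    data.frame(test = k, coding = it$coding, estimate = it$estimate,
               se = it$se, p_interaction = it$p_interaction,
               stringsAsFactors = FALSE)
  }))
}

# Serialise the report bundle as TSV tables + a JSON run log.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  write_tsv(bundle$baseline_table, out("baseline_table.tsv"))
  write_tsv(bundle$qc_report, out("qc_report.tsv"))
  write_tsv(bundle$exclusion_report, out("exclusion_report.tsv"))
  write_tsv(bundle$scores, out("scores.tsv"))
  for (nm in c("stratified_bmi", "stratified_obesity",
               "dichotomized_bmi", "dichotomized_obesity",
               "per_snp_bmi", "incremental_r2")) {
    if (!is.null(bundle[[nm]])) {
      write_tsv(bundle[[nm]], out(paste0(nm, ".tsv")))
    }
  }
  it <- interactions_to_df(bundle)
  if (!is.null(it)) write_tsv(it, out("interaction_tests.tsv"))
  if (!is.null(bundle$auc)) write_tsv(auc_to_df(bundle$auc),
                                      out("auc.tsv"))
  if (!is.null(bundle$auc_comparison)) {
    ac <- bundle$auc_comparison
    write_tsv(data.frame(diff = ac$diff, ci_low = ac$ci_low,
                         ci_high = ac$ci_high, p = ac$p,
                         auc_a = ac$auc_a, auc_b = ac$auc_b,
                         n_boot = ac$n_boot),
              out("auc_comparison.tsv"))
  }
  if (!is.null(bundle$longitudinal)) {
    write_tsv(bundle$longitudinal$slopes, out("longitudinal_slopes.tsv"))
    li <- bundle$longitudinal$interaction
    write_tsv(data.frame(estimate = li$estimate, se = li$se,
                         p_interaction = li$p_interaction,
                         coding = li$coding),
              out("longitudinal_interaction.tsv"))
  }
  jsonlite::write_json(bundle$run_log, out("run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

fmt_mean_sd <- function(x) {
  sprintf("%.1f±%.1f", mean(x, na.rm = TRUE),
          stats::sd(x, na.rm = TRUE))
}

#' Render the baseline characteristics table
#'
#' By sex: n, mean +/- SD of age, baseline BMI and score; activity-level
#' counts with percentages; and, when any subject has follow-up data, a
#' follow-up block with n, age and BMI at the second check.
#'
#' @param data Frame from [prepare_model_data()].
#' @return Data frame with columns `block`, `trait`, `men`, `women`.
#' @export
render_baseline_table <- function(data) {
  stopifnot(nrow(data) > 0)
  men <- data[data$sex == "M", ]
  women <- data[data$sex == "F", ]
  row <- function(block, trait, m, w) {
    data.frame(block = block, trait = trait, men = m, women = w,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("baseline", "n", format(nrow(men)), format(nrow(women))),
    row("baseline", "age_y", fmt_mean_sd(men$age), fmt_mean_sd(women$age)),
    row("baseline", "bmi", fmt_mean_sd(men$bmi), fmt_mean_sd(women$bmi)),
    row("baseline", "score", fmt_mean_sd(men$score),
        fmt_mean_sd(women$score))
  )
  labs <- activity_labels()
  for (lv in 0:3) {
    nm <- sum(men$activity == lv)
    nw <- sum(women$activity == lv)
    tab <- rbind(tab, row(
      "baseline", labs[as.character(lv)],
      sprintf("%d (%.1f%%)", nm, 100 * nm / max(1, nrow(men))),
      sprintf("%d (%.1f%%)", nw, 100 * nw / max(1, nrow(women)))))
  }
  fm <- men[!is.na(men$bmi_followup), ]
  fw <- women[!is.na(women$bmi_followup), ]
  if (nrow(fm) + nrow(fw) > 0) {
    tab <- rbind(
      tab,
      row("followup", "n", format(nrow(fm)), format(nrow(fw))),
      row("followup", "age_y",
          fmt_mean_sd(fm$age + fm$followup_years),
          fmt_mean_sd(fw$age + fw$followup_years)),
      row("followup", "bmi", fmt_mean_sd(fm$bmi_followup),
          fmt_mean_sd(fw$bmi_followup))
    )
  }
  tab
}
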