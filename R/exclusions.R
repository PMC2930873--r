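#' Annual change between baseline and follow-up
#'
#' @param value_baseline,value_followup Measurements at the two checks.
#' @param followup_years Elapsed years, > 0.
#' @return Per-year change; NA (undefined, not zero) where follow-up is
#'   missing.
#' @export
annual_change <- function(value_baseline, value_followup, followup_years) {
  if (any(followup_years <= 0, na.rm = TRUE)) {
    stop("followup_years must be > 0")
  }
  (value_followup - value_baseline) / followup_years
}

#' BMI category
#'
#' underweight: BMI < 18.5; normal: 18.5 <= BMI < 25; overweight_only:
#' 25 <= BMI < 30; obese: BMI >= 30.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Character vector of categories.
#' @export
bmi_category <- function(bmi) {
  out <- rep(NA_character_, length(bmi))
  out[bmi < 18.5] <- "underweight"
  out[bmi >= 18.5 & bmi < 25] <- "normal"
  out[bmi >= 25 & bmi < 30] <- "overweight_only"
  out[bmi >= 30] <- "obese"
  out
}

#' Apply the cohort exclusion rules
#'
#' Drops subjects in order: (1) prevalent type 2 diabetes; (2) missing any
#' required baseline phenotype (sex, age, baseline BMI, baseline waist,
#' occupation; recreational hours are required unless the occupation is
#' heavy, whose level does not depend on them); (3) implausible change,
#' absolute annual BMI change > 2 kg/m^2 or waist change > 7 cm — testable
#' only where follow-up exists, so baseline-only subjects pass vacuously.
#' Both bounds are strict: an annual change of exactly 2 kg/m^2 is
#' retained.  Optionally also drops prevalent cardiovascular disease and
#' cancer (sensitivity analysis).
#'
#' @param records Subject-record data frame.
#' @param sensitivity_cvd_cancer Also exclude prevalent CVD/cancer
#'   (default FALSE).
#' @param bmi_change_max,waist_change_max Annual-change bounds (kg/m^2/y
#'   and cm/y).
#' @return List with `analysis_set` (records retained, plus derived
#'   columns `activity_level`, `annual_bmi_change`, `annual_waist_change`)
#'   and `exclusion_report` (rule, n_excluded, order).
#' @export
apply_exclusions <- function(records, sensitivity_cvd_cancer = FALSE,
                             bmi_change_max = 2, waist_change_max = 7) {
  rec <- records
  report <- data.frame(rule = character(), n_excluded = integer(),
                       order = integer(), stringsAsFactors = FALSE)
  add_rule <- function(name, keep) {
    report <<- rbind(report, data.frame(
      rule = name, n_excluded = sum(!keep), order = nrow(report) + 1L,
      stringsAsFactors = FALSE))
    rec <<- rec[keep, , drop = FALSE]
  }

  add_rule("prevalent_t2d", !(rec$prevalent_t2d %in% 1))

  hours_needed <- rec$occupation != "heavy"
  missing_pheno <- is.na(rec$sex) | is.na(rec$age) |
    is.na(rec$bmi_baseline) | is.na(rec$waist_baseline) |
    is.na(rec$occupation) |
    (hours_needed & is.na(rec$recreation_hours_per_day))
  add_rule("missing_phenotype", !missing_pheno)

  dbmi <- annual_change(rec$bmi_baseline, rec$bmi_followup,
                        rec$followup_years)
  dwaist <- annual_change(rec$waist_baseline, rec$waist_followup,
                          rec$followup_years)
  implausible <- (!is.na(dbmi) & abs(dbmi) > bmi_change_max) |
    (!is.na(dwaist) & abs(dwaist) > waist_change_max)
  add_rule("implausible_change", !implausible)

  if (sensitivity_cvd_cancer) {
    cvd <- if ("prevalent_cvd" %in% names(rec)) rec$prevalent_cvd else 0
    can <- if ("prevalent_cancer" %in% names(rec)) rec$prevalent_cancer else 0
    add_rule("prevalent_cvd_cancer",
             !(cvd %in% 1 | can %in% 1))
  }

  if (!nrow(rec)) stop("all subjects excluded; empty analysis set")

  hrs <- rec$recreation_hours_per_day
  hrs[rec$occupation == "heavy" & is.na(hrs)] <- 0
  rec$activity_level <- classify_activity(rec$occupation, hrs)
  rec$annual_bmi_change <- annual_change(rec$bmi_baseline,
                                         rec$bmi_followup,
                                         rec$followup_years)
  rec$annual_waist_change <- annual_change(rec$waist_baseline,
                                           rec$waist_followup,
                                           rec$followup_years)
  list(analysis_set = rec, exclusion_report = report)
}
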