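#' Incremental variance in BMI explained by the score
#'
#' R-squared of the covariate model (age, age^2, sex) plus the score,
#' minus R-squared of the covariates alone, on complete cases shared by
#' both fits.  Apply within an activity stratum to reproduce stratified
#' explained-variance contrasts.
#'
#' @param data Frame from [prepare_model_data()] (or any frame with
#'   `bmi`, `score`, `age`, `age2`, `sex01`).
#' @return The incremental R-squared (fraction).
#' @export
incremental_r2 <- function(data) {
  fr <- build_frame(data, "bmi", c("score", base_covariates))
  full <- fit_linear(fr, "bmi", c(base_covariates, "score"))
  red <- fit_linear(fr, "bmi", base_covariates)
  summary(full$fit)$r.squared - summary(red$fit)$r.squared
}

#' ROC AUC by the rank (Mann-Whitney) estimator
#'
#' AUC is the probability that a random case outranks a random control
#' under the predictor, estimated from midranks (ties count 1/2).  The
#' 95% CI uses the Hanley-McNeil normal approximation, truncated to
#' \[0, 1\].
#'
#' @param predictor Numeric risk predictor (e.g. fitted probabilities of
#'   a logistic model).
#' @param labels 0/1 (or logical) case labels; both classes required.
#' @param stratum Optional stratum label carried into the result.
#' @return List of class `auc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`, `stratum`.
#' @export
roc_auc <- function(predictor, labels, stratum = NA_character_) {
  if (is.logical(labels)) labels <- as.integer(labels)
  keep <- !is.na(predictor) & !is.na(labels)
  predictor <- predictor[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(predictor, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  structure(list(auc = auc,
                 ci_low = max(0, auc - 1.96 * se),
                 ci_high = min(1, auc + 1.96 * se),
                 se = se, n_cases = n1, n_controls = n0,
                 stratum = stratum),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls%s\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls,
              if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]")))
  invisible(x)
}

#' Obesity discrimination of the score model, by activity stratum
#'
#' Within each stratum, fits the logistic obesity model (obese vs normal
#' weight) on score, age, age^2 and sex, and computes the AUC of its
#' fitted probabilities.  AUC is in-sample by default; `cv_folds` switches
#' to out-of-fold predicted probabilities (seeded fold assignment).
#'
#' @param data Frame from [prepare_model_data()].
#' @param strata Named list of logical stratum masks; defaults to
#'   inactive and combined-active.
#' @param cv_folds Number of cross-validation folds, or NULL (default)
#'   for in-sample evaluation.
#' @param seed RNG seed for fold assignment (ignored without cv).
#' @return List of `auc_result`, one per stratum.
#' @export
auc_by_stratum <- function(data, strata = NULL, cv_folds = NULL,
                           seed = 1L) {
  if (is.null(strata)) {
    strata <- list(inactive = data$activity == 0L,
                   `combined active` = data$activity >= 1L)
  }
  lapply(stats::setNames(names(strata), names(strata)), function(nm) {
    sub <- data[strata[[nm]] & !is.na(data$obese), , drop = FALSE]
    terms <- c("score", base_covariates)
    if (is.null(cv_folds)) {
      model <- fit_logistic(sub, "obese", terms)
      prob <- stats::fitted(model$fit)
      roc_auc(prob, sub$obese, stratum = nm)
    } else {
      set.seed(seed)
      fold <- sample(rep_len(seq_len(cv_folds), nrow(sub)))
      prob <- rep(NA_real_, nrow(sub))
      for (f in seq_len(cv_folds)) {
        train <- sub[fold != f, , drop = FALSE]
        m <- fit_logistic(train, "obese", terms)
        prob[fold == f] <- stats::predict(m$fit,
                                          newdata = sub[fold == f, ],
                                          type = "response")
      }
      roc_auc(prob, sub$obese, stratum = nm)
    }
  })
}

#' Bootstrap comparison of two strata's AUCs
#'
#' Resamples subjects with replacement within each stratum independently,
#' recomputes both AUCs, and reports the observed difference
#' (`a - b`), a percentile bootstrap CI, and a two-sided p-value from the
#' bootstrap distribution's overlap with zero.
#'
#' @param predictor_a,labels_a Predictor and 0/1 labels, stratum A.
#' @param predictor_b,labels_b Same for stratum B.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return List of class `auc_comparison`: `diff`, `ci_low`, `ci_high`,
#'   `p`, `auc_a`, `auc_b`, `n_boot`.
#' @export
compare_auc <- function(predictor_a, labels_a, predictor_b, labels_b,
                        n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  a <- roc_auc(predictor_a, labels_a)
  b <- roc_auc(predictor_b, labels_b)
  set.seed(seed)
  na <- length(predictor_a); nb <- length(predictor_b)
  boot <- vapply(seq_len(n_boot), function(i) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- sample.int(nb, nb, replace = TRUE)
    # degenerate resamples (one class only) are redrawn implicitly by NA
    aa <- tryCatch(roc_auc(predictor_a[ia], labels_a[ia])$auc,
                   error = function(e) NA_real_)
    bb <- tryCatch(roc_auc(predictor_b[ib], labels_b[ib])$auc,
                   error = function(e) NA_real_)
    aa - bb
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  nb_eff <- length(boot)
  p <- min(1, 2 * min(sum(boot <= 0) + 1, sum(boot >= 0) + 1) /
             (nb_eff + 1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(diff = a$auc - b$auc, ci_low = ci[1], ci_high = ci[2],
                 p = p, auc_a = a$auc, auc_b = b$auc, n_boot = nb_eff),
            class = "auc_comparison")
}
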