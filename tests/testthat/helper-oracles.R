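# Independent oracles used across the suite.  Each deliberately takes a
# different computational route than the package implementation.

# OLS via explicit normal equations (X'X)^{-1} X'y.
oracle_lm <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  list(beta = drop(beta), se = se, df = df)
}

# Logistic MLE via damped Newton-Raphson on the log-likelihood.
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    damp <- 1
    ll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e)))
    }
    while (ll(beta + damp * step) < ll(beta) && damp > 1e-8) {
      damp <- damp / 2
    }
    beta <- beta + damp * step
    if (max(abs(damp * step)) < tol) break
  }
  beta
}

# AUC by exhaustive case-control pair enumeration (ties count 1/2).
oracle_auc <- function(predictor, labels) {
  cases <- predictor[labels == 1]
  controls <- predictor[labels == 0]
  tot <- 0
  for (ca in cases) {
    tot <- tot + sum(ca > controls) + 0.5 * sum(ca == controls)
  }
  tot / (length(cases) * length(controls))
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(predictor, labels) {
  thr <- sort(unique(predictor), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(predictor[labels == 1] >= t),
                numeric(1))
  fpr <- vapply(thr, function(t) mean(predictor[labels == 0] >= t),
                numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# HWE chi-square p-value recomputed from scratch; p-value taken through
# the normal tail rather than pchisq (chi2_1 = Z^2).
oracle_hwe <- function(n_rr, n_rh, n_oo) {
  n <- n_rr + n_rh + n_oo
  p <- (2 * n_rr + n_rh) / (2 * n)
  if (p <= 0 || p >= 1) return(NA_real_)
  e <- n * c(p * p, 2 * p * (1 - p), (1 - p) * (1 - p))
  o <- c(n_rr, n_rh, n_oo)
  chi2 <- sum((o - e)^2 / e)
  2 * stats::pnorm(-sqrt(chi2))
}

# Build a small genotype panel from a dosage matrix.
tiny_panel <- function(dosage, ids = NULL) {
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dosage)))
  genotype_panel(dosage, ids)
}

# Simulate a cohort and carry it through exclusions + scoring into the
# modelling frame (no SNP QC, so the panel stays intact for unit tests).
sim_model_data <- function(config) {
  cohort <- simulate_cohort(config)
  excl <- apply_exclusions(cohort$records)
  keep <- match(excl$analysis_set$subject_id, cohort$panel$subject_ids)
  panel <- genotype_panel(cohort$panel$dosage[keep, , drop = FALSE],
                          excl$analysis_set$subject_id)
  scores <- compute_scores(panel)
  list(data = prepare_model_data(excl$analysis_set, scores),
       panel = panel, cohort = cohort, excl = excl)
}

# Quiet config for fast deterministic tests: no missingness, no disease,
# everyone followed up.
quiet_config <- function(n_subjects, seed, ...) {
  args <- list(n_subjects = n_subjects, seed = seed,
               genotype_missing_rate = 0, dropout_rate = 0,
               prevalence_t2d = 0, prevalence_cvd = 0,
               prevalence_cancer = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
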