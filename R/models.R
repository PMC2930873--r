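#' Fit an ordinary least-squares linear model
#'
#' Complete-case OLS of `outcome` on the given design terms, with
#' two-sided t-based p-values.  Terms are column names of `data` or `:`
#' products of them.
#'
#' @param data Data frame holding all referenced columns.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of design terms (intercept always
#'   included).
#' @return A `model_result` list: `outcome`, `kind = "linear"`,
#'   `coefficients` (term, estimate, se, p), `n_used`, `covariates`,
#'   `fit` (the underlying lm object).
#' @export
fit_linear <- function(data, outcome, terms) {
  fr <- build_frame(data, outcome, terms)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(terms, collapse = " + ")))
  if (nrow(fr) <= length(terms) + 1L) {
    stop("too few complete cases (", nrow(fr), ") for ", length(terms),
         " terms")
  }
  fit <- stats::lm(fml, data = fr)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  res <- list(
    outcome = outcome,
    kind = "linear",
    coefficients = data.frame(
      term = rownames(sm),
      estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"],
      p = sm[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    n_used = nrow(fr),
    covariates = terms,
    fit = fit
  )
  class(res) <- "model_result"
  res
}

#' Fit a logistic regression model
#'
#' Complete-case maximum-likelihood logistic regression with Wald
#' p-values, odds ratios and 95% CIs (`exp(estimate +/- 1.96 se)`).
#' Convergence tolerance 1e-8, at most 100 IRLS iterations; apparent
#' complete separation raises an error rather than returning silently
#' divergent estimates.
#'
#' @inheritParams fit_linear
#' @param outcome Name of a 0/1 (or logical) outcome column; both classes
#'   must be present.
#' @return A `model_result` with `kind = "logistic"` and additional
#'   coefficient columns `or`, `or_low`, `or_high`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  fr <- build_frame(data, outcome, terms)
  y <- fr[[outcome]]
  if (is.logical(y)) fr[[outcome]] <- y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("logistic outcome must be 0/1")
  if (length(unique(y)) < 2L) {
    stop("logistic outcome needs both classes present")
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(terms, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = fr,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15)) {
    stop("logistic fit did not converge (possible complete separation)")
  }
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  res <- list(
    outcome = outcome,
    kind = "logistic",
    coefficients = data.frame(
      term = rownames(sm),
      estimate = est,
      se = se,
      p = sm[, "Pr(>|z|)"],
      or = exp(est),
      or_low = exp(est - 1.96 * se),
      or_high = exp(est + 1.96 * se),
      row.names = NULL, stringsAsFactors = FALSE),
    n_used = nrow(fr),
    covariates = terms,
    fit = fit
  )
  class(res) <- "model_result"
  res
}

# Complete-case frame over the columns a set of design terms references.
build_frame <- function(data, outcome, terms) {
  cols <- unique(c(outcome, unlist(strsplit(terms, ":", fixed = TRUE))))
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  }
  fr <- data[, cols, drop = FALSE]
  fr[stats::complete.cases(fr), , drop = FALSE]
}

#' Extract one coefficient row from a model result
#'
#' @param model A `model_result`.
#' @param term Term name as it appears in the coefficient table.
#' @return A one-row data frame.
#' @export
coef_row <- function(model, term) {
  tab <- model$coefficients
  i <- match(term, tab$term)
  if (is.na(i)) stop("term '", term, "' not in model: ",
                     paste(tab$term, collapse = ", "))
  tab[i, , drop = FALSE]
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s model of %s (n = %d)\n", x$kind, x$outcome, x$n_used))
  print(x$coefficients, digits = 4)
  invisible(x)
}
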