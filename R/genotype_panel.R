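#' Construct a genotype panel
#'
#' A genotype panel holds the subject x SNP risk-allele dosage matrix
#' (entries 0, 1, 2 or NA for missing) together with per-SNP QC
#' statistics: call rate and the Hardy-Weinberg equilibrium p-value
#' computed from the non-missing genotype counts.
#'
#' @param dosage Integer matrix, subjects in rows, SNPs in columns; column
#'   names are SNP ids; entries in \{0, 1, 2, NA\}.
#' @param subject_ids Character vector of subject identifiers, one per row.
#' @return A list of class `genotype_panel` with elements `subject_ids`,
#'   `snp_ids`, `dosage`, `call_rate`, `hwe_p`.
#' @export
genotype_panel <- function(dosage, subject_ids = rownames(dosage)) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  if (is.null(colnames(dosage))) stop("dosage must have SNP column names")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("s%04d", seq_len(nrow(dosage)))
  }
  if (length(subject_ids) != nrow(dosage)) {
    stop("subject_ids length must equal the number of dosage rows")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf("dosage entries must be 0, 1, 2 or NA (offending value %s)",
                 dosage[idx]))
  }
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- subject_ids
  call_rate <- 1 - colMeans(is.na(dosage))
  hwe_p <- vapply(seq_len(ncol(dosage)), function(j) {
    g <- dosage[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    suppressWarnings(
      as.numeric(hwe_test(sum(g == 2L), sum(g == 1L), sum(g == 0L)))
    )
  }, numeric(1))
  names(call_rate) <- names(hwe_p) <- colnames(dosage)
  structure(list(subject_ids = subject_ids, snp_ids = colnames(dosage),
                 dosage = dosage, call_rate = call_rate, hwe_p = hwe_p),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d subjects x %d SNPs\n",
              length(x$subject_ids), length(x$snp_ids)))
  cat(sprintf("  call rate: %.3f-%.3f; HWE p: %.3g-%.3g\n",
              min(x$call_rate), max(x$call_rate),
              min(x$hwe_p), max(x$hwe_p)))
  invisible(x)
}

#' Filter SNPs on genotyping quality
#'
#' Drops SNPs whose call rate or Hardy-Weinberg p-value does not exceed
#' the thresholds (strict inequalities: a call rate of exactly 0.95
#' fails).
#'
#' @param panel A `genotype_panel`.
#' @param call_rate_min Minimum call rate, exclusive (default 0.95).
#' @param hwe_p_min Minimum HWE p-value, exclusive (default 0.05).
#' @return A list with the filtered `panel` and a `qc_report` data frame
#'   (snp_id, call_rate, hwe_p, pass, reason).
#' @export
qc_filter <- function(panel, call_rate_min = 0.95, hwe_p_min = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  pass_cr <- panel$call_rate > call_rate_min
  pass_hwe <- panel$hwe_p > hwe_p_min
  pass <- pass_cr & pass_hwe
  reason <- rep("", length(pass))
  reason[!pass_cr] <- "call_rate"
  reason[!pass_hwe] <- ifelse(nzchar(reason[!pass_hwe]),
                              "call_rate;hwe", "hwe")
  report <- data.frame(
    snp_id = panel$snp_ids,
    call_rate = unname(panel$call_rate),
    hwe_p = unname(panel$hwe_p),
    pass = pass,
    reason = reason,
    stringsAsFactors = FALSE
  )
  if (!any(pass)) stop("all SNPs fail QC; empty panel")
  kept <- genotype_panel(panel$dosage[, pass, drop = FALSE],
                         panel$subject_ids)
  list(panel = kept, qc_report = report)
}
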