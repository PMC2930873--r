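#' Compute the genetic predisposition score
#'
#' The score is the unweighted count of BMI-increasing alleles over the
#' panel's SNPs (0-24 for the 12-SNP panel).  A subject missing genotypes
#' for at most `max_missing` SNPs has each missing dosage substituted by
#' that SNP's mean dosage among genotyped subjects (so the score becomes
#' fractional); with more missing SNPs the score is undefined
#' (`complete = FALSE`).
#'
#' @param panel A QC-passed `genotype_panel`.  Substitution means are
#'   computed from this panel, so pass the analysis cohort (post
#'   exclusions), not the raw file.
#' @param max_missing Maximum number of substitutable missing genotypes
#'   per subject (default 3).
#' @return A data frame with columns `subject_id`, `score`, `n_missing`,
#'   `n_substituted`, `complete`.
#' @export
compute_scores <- function(panel, max_missing = 3L) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosage
  n_called <- colSums(!is.na(dos))
  if (any(n_called == 0)) {
    stop("SNP(s) with zero non-missing calls: ",
         paste(panel$snp_ids[n_called == 0], collapse = ", "))
  }
  m_j <- colMeans(dos, na.rm = TRUE)
  n_missing <- rowSums(is.na(dos))
  observed_sum <- rowSums(dos, na.rm = TRUE)
  miss_mat <- is.na(dos)
  subst_sum <- as.vector(miss_mat %*% m_j)
  complete <- n_missing <= max_missing
  score <- ifelse(complete, observed_sum + subst_sum, NA_real_)
  data.frame(
    subject_id = panel$subject_ids,
    score = score,
    n_missing = n_missing,
    n_substituted = ifelse(complete, n_missing, 0L),
    complete = complete,
    stringsAsFactors = FALSE
  )
}
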