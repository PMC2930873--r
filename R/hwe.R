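#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions p^2 : 2pq : q^2 implied by the sample allele
#' frequency, without continuity correction (the standard genotyping-QC
#' form at cohort sample sizes).
#'
#' @param n_hom_risk Count of risk-allele homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_other Count of other-allele homozygotes.
#' @return The chi-square p-value in \[0, 1\].  A monomorphic SNP (sample
#'   allele frequency 0 or 1) returns 1 with a warning, carried as
#'   attribute `monomorphic = TRUE`.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions -> p = 1
#' @export
hwe_test <- function(n_hom_risk, n_het, n_hom_other) {
  counts <- c(n_hom_risk, n_het, n_hom_other)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be > 0")
  p <- (2 * n_hom_risk + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic SNP: HWE test undefined, returning p = 1")
    return(structure(1, monomorphic = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(stats::pchisq(chi2, df = 1, lower.tail = FALSE),
            chi2 = chi2, monomorphic = FALSE)
}
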