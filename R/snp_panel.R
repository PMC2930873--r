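#' Define one obesity-susceptibility SNP
#'
#' A SNP specification names the variant, its BMI-increasing (risk) allele,
#' the other allele, and -- for simulation only -- the population frequency
#' of the risk allele.
#'
#' @param snp_id Variant identifier (e.g. an rs number).
#' @param risk_allele Single base whose dosage is counted (the
#'   BMI-increasing allele).
#' @param other_allele The other allele; must differ from `risk_allele`.
#' @param risk_allele_frequency Risk-allele frequency in (0, 1); used only
#'   by the cohort simulator.
#' @return A one-row data frame of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, risk_allele, other_allele,
                     risk_allele_frequency = NA_real_) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L, nzchar(snp_id))
  risk_allele <- toupper(risk_allele)
  other_allele <- toupper(other_allele)
  if (identical(risk_allele, other_allele)) {
    stop("risk_allele and other_allele must differ for ", snp_id)
  }
  if (!is.na(risk_allele_frequency) &&
      (risk_allele_frequency <= 0 || risk_allele_frequency >= 1)) {
    stop("risk_allele_frequency must lie strictly in (0, 1) for ", snp_id)
  }
  out <- data.frame(
    snp_id = snp_id,
    risk_allele = risk_allele,
    other_allele = other_allele,
    risk_allele_frequency = risk_allele_frequency,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_spec", class(out))
  out
}

#' The default 12-SNP obesity-susceptibility panel
#'
#' Twelve GWAS-established BMI loci (near/in NEGR1, SEC16B, TMEM18, ETV5,
#' GNPDA2, BDNF, MTCH2, FAIM2, SH2B1, FTO, MC4R and KCTD15).  Risk-allele
#' frequencies are synthetic defaults of realistic GWAS magnitude chosen so
#' that the expected unweighted score, 2 * sum(p), is about 11.2 with
#' median 11; they parameterise the simulator only and carry no assay
#' information.
#'
#' @return A 12-row `snp_spec` data frame.
#' @export
default_snp_panel <- function() {
  panel <- rbind(
    snp_spec("rs3101336",  "C", "T", 0.61), # NEGR1
    snp_spec("rs10913469", "C", "T", 0.20), # SEC16B
    snp_spec("rs6548238",  "C", "T", 0.83), # TMEM18
    snp_spec("rs7647305",  "C", "T", 0.79), # ETV5
    snp_spec("rs10938397", "G", "A", 0.43), # GNPDA2
    snp_spec("rs925946",   "T", "G", 0.30), # BDNF
    snp_spec("rs10838738", "G", "A", 0.34), # MTCH2
    snp_spec("rs7132908",  "A", "G", 0.38), # FAIM2
    snp_spec("rs7498665",  "G", "A", 0.40), # SH2B1
    snp_spec("rs1121980",  "A", "G", 0.43), # FTO
    snp_spec("rs17782313", "C", "T", 0.24), # MC4R
    snp_spec("rs368794",   "A", "T", 0.67)  # KCTD15
  )
  class(panel) <- c("snp_spec", "data.frame")
  panel
}

#' Read a SNP-definition sheet
#'
#' Tab-separated with columns `snp_id`, `risk_allele`, `other_allele` and
#' optionally `risk_allele_frequency`.
#'
#' @param path Path to the TSV sheet.
#' @return A `snp_spec` data frame.
#' @export
read_snp_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "risk_allele", "other_allele")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("SNP sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"risk_allele_frequency" %in% names(tab)) {
    tab$risk_allele_frequency <- NA_real_
  }
  specs <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    snp_spec(tab$snp_id[i], tab$risk_allele[i], tab$other_allele[i],
             tab$risk_allele_frequency[i])
  }))
  class(specs) <- c("snp_spec", "data.frame")
  specs
}

#' Write a SNP-definition sheet
#'
#' @param specs A `snp_spec` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_sheet <- function(specs, path) {
  utils::write.table(as.data.frame(specs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
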