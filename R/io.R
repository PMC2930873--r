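#' Read a genotype dosage table
#'
#' Tab-separated, header `subject_id` followed by SNP columns; cells in
#' \{0, 1, 2, NA\}.  Columns are matched to `snp_specs$snp_id` by name
#' (any order in the file) and returned in spec order.
#'
#' @param path Path to the genotype TSV.
#' @param snp_specs `snp_spec` data frame naming the expected SNPs.
#' @return A `genotype_panel`.
#' @export
read_genotype_table <- function(path, snp_specs) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
  if (!"subject_id" %in% names(tab)) {
    stop("genotype table must have a subject_id column")
  }
  snp_cols <- setdiff(names(tab), "subject_id")
  unknown <- setdiff(snp_cols, snp_specs$snp_id)
  if (length(unknown)) {
    stop("unknown SNP column(s) in genotype table: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(snp_specs$snp_id, snp_cols)
  if (length(absent)) {
    stop("genotype table is missing SNP column(s): ",
         paste(absent, collapse = ", "))
  }
  dosage <- matrix(NA_integer_, nrow(tab), nrow(snp_specs),
                   dimnames = list(NULL, snp_specs$snp_id))
  for (snp in snp_specs$snp_id) {
    cell <- tab[[snp]]
    ok <- cell %in% c("0", "1", "2", "NA", "")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf(
        "invalid dosage '%s' at row %d, column %s (must be 0, 1, 2 or NA)",
        cell[i], i, snp))
    }
    val <- suppressWarnings(as.integer(cell))
    dosage[, snp] <- val
  }
  genotype_panel(dosage, tab$subject_id)
}

#' Read a phenotype table
#'
#' Tab-separated, one row per subject, with columns `subject_id`, `sex`
#' (M/F), `age`, `bmi_baseline`, `bmi_followup`, `waist_baseline`,
#' `waist_followup`, `followup_years`, `occupation`,
#' `recreation_hours_per_day`, `prevalent_t2d` and optionally
#' `prevalent_cvd`, `prevalent_cancer`.
#'
#' @param path Path to the phenotype TSV.
#' @return A subject-record data frame.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "bmi_baseline", "bmi_followup",
            "waist_baseline", "waist_followup", "followup_years",
            "occupation", "recreation_hours_per_day", "prevalent_t2d")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad_sex <- !tab$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("sex must be M or F (row ", which(bad_sex)[1], ")")
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab
}

#' Read genotypes from a minimal VCF
#'
#' Expects one record per SNP with GT fields.  For each SNP in
#' `snp_specs`, the record's REF/ALT must together contain the spec's two
#' alleles; the risk allele may be either REF or ALT and orientation is
#' resolved per record.  `./.` becomes missing.
#'
#' @param path Path to a VCF 4.x file.
#' @param snp_specs `snp_spec` data frame naming SNPs and risk alleles.
#' @return A `genotype_panel` with SNPs in spec order.
#' @export
read_vcf <- function(path, snp_specs) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  ids <- rownames(gt)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(seq_along(ids), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    paste(as.character(a), collapse = ",")
  }, character(1))
  subjects <- colnames(gt)
  dosage <- matrix(NA_integer_, length(subjects), nrow(snp_specs),
                   dimnames = list(NULL, snp_specs$snp_id))
  for (k in seq_len(nrow(snp_specs))) {
    snp <- snp_specs$snp_id[k]
    i <- match(snp, ids)
    if (is.na(i)) stop("SNP ", snp, " not present in VCF")
    alleles <- c(ref[i], alt[i])
    want <- c(snp_specs$risk_allele[k], snp_specs$other_allele[k])
    if (!setequal(alleles, want)) {
      stop(sprintf("allele mismatch for %s: VCF has %s/%s, spec has %s/%s",
                   snp, ref[i], alt[i], want[1], want[2]))
    }
    risk_idx <- if (ref[i] == snp_specs$risk_allele[k]) "0" else "1"
    dosage[, k] <- vapply(gt[i, ], function(call) {
      parts <- strsplit(call, "[/|]")[[1]]
      if (any(parts == ".")) return(NA_integer_)
      sum(parts == risk_idx)
    }, integer(1))
  }
  genotype_panel(dosage, subjects)
}
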