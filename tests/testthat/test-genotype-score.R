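specs3 <- rbind(snp_spec("snpA", "A", "G", 0.3),
                snp_spec("snpB", "C", "T", 0.5),
                snp_spec("snpC", "G", "A", 0.7))

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_genotype_table parses dosages and rejects bad cells", {
  path <- write_tsv_lines(c("subject_id\tsnpA\tsnpB\tsnpC",
                            "s1\t0\t1\t2",
                            "s2\tNA\t2\t0"))
  panel <- read_genotype_table(path, specs3)
  expect_identical(unname(panel$dosage[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(panel$dosage[2, "snpA"]))

  bad <- write_tsv_lines(c("subject_id\tsnpA\tsnpB\tsnpC",
                           "s1\t0\t3\t2"))
  expect_error(read_genotype_table(bad, specs3), "row 1, column snpB")

  unknown <- write_tsv_lines(c("subject_id\tsnpA\tsnpX\tsnpC",
                               "s1\t0\t1\t2"))
  expect_error(read_genotype_table(unknown, specs3), "unknown SNP")
})

test_that("scores are invariant to SNP column order", {
  path <- write_tsv_lines(c("subject_id\tsnpC\tsnpA\tsnpB",
                            "s1\t2\t0\t1",
                            "s2\t0\tNA\t2"))
  panel <- read_genotype_table(path, specs3)
  expect_identical(panel$snp_ids, specs3$snp_id)
  expect_identical(unname(panel$dosage[1, ]), c(0L, 1L, 2L))
})

test_that("hwe_test matches hand computations", {
  expect_equal(as.numeric(hwe_test(25, 50, 25)), 1)
  expect_equal(attr(hwe_test(25, 50, 25), "chi2"), 0)
  expect_warning(p_mono <- hwe_test(0, 0, 100), "monomorphic")
  expect_equal(as.numeric(p_mono), 1)
  # (30, 40, 30): p_hat = 0.5, expected (25, 50, 25), chi2 = 4
  p <- hwe_test(30, 40, 30)
  expect_equal(attr(p, "chi2"), 4)
  expect_equal(as.numeric(p), stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(p), 4), 0.0455)
})

test_that("hwe_test agrees with the brute-force oracle on all small triples", {
  for (n in 1:30) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        cc <- n - a - b
        expected <- oracle_hwe(a, b, cc)
        if (is.na(expected)) next  # monomorphic
        expect_equal(as.numeric(hwe_test(a, b, cc)), expected,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("qc_filter applies strict thresholds", {
  set.seed(42)
  n <- 200
  dos <- cbind(
    good = stats::rbinom(n, 2, 0.4),
    low_cr = stats::rbinom(n, 2, 0.4),
    exact_cr = stats::rbinom(n, 2, 0.4)
  )
  dos[1:12, "low_cr"] <- NA          # call rate 0.94
  dos[1:10, "exact_cr"] <- NA        # call rate exactly 0.95
  panel <- tiny_panel(dos)
  res <- qc_filter(panel)
  expect_identical(res$panel$snp_ids, "good")
  rep <- res$qc_report
  expect_false(rep$pass[rep$snp_id == "low_cr"])
  expect_false(rep$pass[rep$snp_id == "exact_cr"])  # strict ">"
  expect_match(rep$reason[rep$snp_id == "low_cr"], "call_rate")

  # a panel where everything passes is unchanged
  clean <- tiny_panel(cbind(a = stats::rbinom(n, 2, 0.3),
                            b = stats::rbinom(n, 2, 0.6)))
  res2 <- qc_filter(clean)
  expect_identical(res2$panel$dosage, clean$dosage)

  # HWE failure is dropped too: all heterozygotes is maximally off-HWE
  hwe_bad <- tiny_panel(cbind(ok = stats::rbinom(n, 2, 0.5),
                              het = rep(1L, n)))
  res3 <- qc_filter(hwe_bad)
  expect_identical(res3$panel$snp_ids, "ok")

  expect_error(qc_filter(tiny_panel(cbind(het = rep(1L, n)))),
               "all SNPs fail")
})

test_that("compute_scores counts alleles and substitutes means", {
  dos12 <- matrix(2L, nrow = 1, ncol = 12,
                  dimnames = list(NULL, paste0("s", 1:12)))
  expect_equal(compute_scores(tiny_panel(dos12))$score, 24)
  expect_equal(compute_scores(tiny_panel(dos12 * 0L))$score, 0)

  # hand-built panel: subject 1 misses snp1 and snp2 whose substitution
  # means are 0.8 and 1.2; its observed dosages sum to 9
  dos <- matrix(0L, nrow = 6, ncol = 12,
                dimnames = list(NULL, paste0("s", 1:12)))
  dos[2:6, 1] <- c(1L, 1L, 1L, 1L, 0L)          # mean 0.8
  dos[2:6, 2] <- c(2L, 1L, 1L, 1L, 1L)          # mean 1.2
  dos[1, 3:12] <- c(2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)  # sum 9
  dos[1, 1:2] <- NA
  res <- compute_scores(tiny_panel(dos))
  expect_equal(res$score[1], 11.0)
  expect_equal(res$n_substituted[1], 2L)
  expect_true(res$complete[1])

  # more than 3 missing -> undefined score
  dos[1, 1:4] <- NA
  res4 <- compute_scores(tiny_panel(dos))
  expect_false(res4$complete[1])
  expect_true(is.na(res4$score[1]))
  expect_equal(res4$n_missing[1], 4L)

  # integer score whenever nothing was substituted
  expect_true(all(res$score[res$n_substituted == 0] ==
                    round(res$score[res$n_substituted == 0])))

  # a SNP with zero non-missing calls cannot form a substitution mean
  dos_all_na <- matrix(NA_integer_, nrow = 3, ncol = 2,
                       dimnames = list(NULL, c("a", "b")))
  dos_all_na[, 2] <- 1L
  expect_error(compute_scores(tiny_panel(dos_all_na)), "zero non-missing")
})

test_that("substituted and complete scores agree under random missingness", {
  cfg <- quiet_config(20000, seed = 41, genotype_missing_rate = 0.04)
  panel <- simulate_genotypes(cfg)
  scores <- compute_scores(panel)
  sub <- scores$score[scores$complete & scores$n_substituted > 0]
  full <- scores$score[scores$n_missing == 0]
  se <- sqrt(stats::var(sub) / length(sub) +
               stats::var(full) / length(full))
  expect_lt(abs(mean(sub) - mean(full)), 3 * se)
})

test_that("read_vcf resolves orientation and missingness", {
  specs <- rbind(snp_spec("rs_alt", "A", "G"),   # risk allele is ALT
                 snp_spec("rs_ref", "C", "T"))   # risk allele is REF
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs_alt", "G", "A", ".", ".", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rs_ref", "C", "T", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  panel <- read_vcf(path, specs)
  expect_identical(unname(panel$dosage[, "rs_alt"]), c(1L, 2L, NA))
  # REF C is the risk allele: 0/0 -> 2 copies, 1/1 -> 0
  expect_identical(unname(panel$dosage[, "rs_ref"]), c(2L, 1L, 0L))

  # allele mismatch and absent SNP are both errors
  expect_error(read_vcf(path, rbind(snp_spec("rs_alt", "A", "C"))),
               "allele mismatch")
  expect_error(read_vcf(path, rbind(snp_spec("rs_gone", "A", "G"))),
               "not present")
})
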