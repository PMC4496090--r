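test_that("panel validation enforces structural invariants", {
  panel <- data.frame(snp_id = c("rs1", "rs2"), locus = c("L1", "L2"),
                      risk_allele = c("A", "C"), other_allele = c("G", "T"),
                      source_trait = c("T2DM", "fasting_glucose"),
                      stringsAsFactors = FALSE)
  ok <- validate_snp_panel(panel)
  expect_s3_class(ok, "snp_panel")
  expect_equal(ok$weight, c(1, 1))

  dup <- panel; dup$snp_id <- c("rs1", "rs1")
  expect_error(validate_snp_panel(dup), "duplicate")
  same <- panel; same$other_allele[1] <- "A"
  expect_error(validate_snp_panel(same), "risk_allele equals")
  weak <- panel; weak$proxy_r2 <- c(0.85, NA)
  expect_error(validate_snp_panel(weak), "proxy_r2")
  badtrait <- panel; badtrait$source_trait[2] <- "BMI"
  expect_error(validate_snp_panel(badtrait), "source_trait")
})

test_that("snp_call_rate counts non-missing cells and flags the threshold", {
  g <- make_geno(100, c(0, 10, 6))
  expect_equal(snp_call_rate(g, "s01"), 1.0)
  expect_equal(snp_call_rate(g, "s02"), 0.90)
  expect_equal(snp_call_rate(g, "s03"), 0.94)
  # enumerate cells directly as an independent check
  expect_equal(snp_call_rate(g, "s03"),
               sum(!is.na(unclass(g)[, "s03"])) / nrow(g))
  expect_lt(snp_call_rate(g, "s03"), 0.95)
  expect_error(snp_call_rate(g, "nope"), "unknown snp_id")
})

test_that("SNP QC drops exactly the low-call-rate SNPs", {
  # 25-SNP panel with 4 SNPs below the 95% call-rate threshold
  miss <- rep(0, 25); miss[c(3, 9, 14, 22)] <- 6    # 94% call rate
  g <- make_geno(100, miss)
  res <- apply_snp_qc(g, 0.95)
  expect_equal(ncol(res$matrix), 21)
  expect_setequal(res$report$excluded_snps$snp_id,
                  sprintf("s%02d", c(3, 9, 14, 22)))
  expect_true(all(res$report$excluded_snps$call_rate < 0.95))

  # nothing below threshold: identity
  clean <- make_geno(50, rep(0, 5))
  res2 <- apply_snp_qc(clean, 0.95)
  expect_equal(unclass(res2$matrix), unclass(clean))
  # a vanishingly small threshold retains everything
  res3 <- apply_snp_qc(g, 1e-9)
  expect_equal(ncol(res3$matrix), 25)
  expect_error(apply_snp_qc(g, 0), "call_rate_threshold")
  allbad <- make_geno(10, c(9, 9))
  expect_error(apply_snp_qc(allbad, 0.95), "empty panel")
})

test_that("individual QC excludes at >= max_failed missing genotypes", {
  counts <- matrix(1, nrow = 4, ncol = 5,
                   dimnames = list(paste0("i", 1:4), paste0("s", 1:5)))
  counts[1, 1:3] <- NA  # 3 missing -> excluded at threshold 3
  counts[2, 1:2] <- NA  # 2 missing -> retained
  g <- geno_matrix(counts)
  res <- apply_individual_qc(g, max_failed = 3)
  expect_setequal(rownames(res$matrix), c("i2", "i3", "i4"))
  expect_equal(res$report$excluded_individuals$individual, "i1")
  expect_equal(res$report$excluded_individuals$n_missing, 3)

  full <- geno_matrix(matrix(2, 3, 3,
                             dimnames = list(paste0("i", 1:3),
                                             paste0("s", 1:3))))
  expect_equal(unclass(apply_individual_qc(full, 3)$matrix), unclass(full))
})

test_that("mean imputation fills with the observed mean and preserves it", {
  counts <- matrix(c(0, 1, 2, 1, NA,
                     2, 2, 2, 2, 2), ncol = 2,
                   dimnames = list(paste0("i", 1:5), c("a", "b")))
  g <- geno_matrix(counts)
  imp <- impute_missing_mean(g)
  expect_equal(unclass(imp)["i5", "a"], 1.0)
  expect_equal(unclass(imp)[, "b"], unclass(g)[, "b"])  # untouched
  # observed mean is preserved exactly per SNP
  expect_equal(mean(unclass(imp)[, "a"]), mean(counts[, "a"], na.rm = TRUE))

  # property: over random matrices, imputation preserves each SNP's
  # observed mean and bounds every score between observed-only and
  # observed + 2 * n_imputed
  for (seed in 1:5) {
    g <- make_geno(40, c(0, 3, 7, 1), seed = seed)
    imp <- impute_missing_mean(g)
    raw <- unclass(g); fil <- unclass(imp)
    for (j in seq_len(ncol(raw))) {
      expect_equal(mean(fil[, j]), mean(raw[, j], na.rm = TRUE))
    }
    obs_sum <- rowSums(raw, na.rm = TRUE)
    n_imp <- rowSums(is.na(raw))
    score <- compute_gps(imp)$gps
    expect_true(all(score >= obs_sum - 1e-12))
    expect_true(all(score <= obs_sum + 2 * n_imp + 1e-12))
  }

  empty <- geno_matrix(matrix(NA_real_, 3, 1,
                              dimnames = list(paste0("i", 1:3), "a")))
  expect_error(impute_missing_mean(empty), "zero observed")
})

test_that("the predisposition score is a (weighted) risk-allele sum", {
  counts <- matrix(c(0, 1, 2), nrow = 1,
                   dimnames = list("i1", c("a", "b", "c")))
  g <- geno_matrix(counts)
  expect_equal(compute_gps(g)$gps, 3)
  zero <- geno_matrix(matrix(0, 2, 3,
                             dimnames = list(c("i1", "i2"),
                                             c("a", "b", "c"))))
  expect_equal(compute_gps(zero)$gps, c(0, 0))
  top <- geno_matrix(matrix(2, 1, 21,
                            dimnames = list("i1", sprintf("s%02d", 1:21))))
  expect_equal(compute_gps(top)$gps, 42)

  w <- c(a = 2, b = 0.5, c = 1)
  expect_equal(compute_gps(g, weights = w)$gps, 0 * 2 + 1 * 0.5 + 2 * 1)

  miss <- geno_matrix(matrix(c(1, NA), 1, 2,
                             dimnames = list("i1", c("a", "b"))))
  expect_error(compute_gps(miss), "missing cells")
})

test_that("the score is equivariant to individual and SNP permutations", {
  g <- make_geno(30, rep(0, 6), seed = 9)
  base <- compute_gps(g)
  withr::with_seed(1, {
    pi_ind <- sample(nrow(g)); pi_snp <- sample(ncol(g))
  })
  perm <- geno_matrix(unclass(g)[pi_ind, pi_snp])
  permuted <- compute_gps(perm)
  expect_equal(permuted$gps, base$gps[pi_ind])
  expect_equal(permuted$individual, base$individual[pi_ind])
})

test_that("genotype readers orient counts to the panel risk allele", {
  panel <- validate_snp_panel(data.frame(
    snp_id = c("rs1", "rs2"), locus = c("L1", "L2"),
    risk_allele = c("A", "C"), other_allele = c("G", "T"),
    source_trait = "T2DM", stringsAsFactors = FALSE))

  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,rs1,rs2", "i1,0,2", "i2,1,", "i3,2,1"), csv)
  g <- read_genotypes_csv(csv, panel)
  expect_equal(unclass(g)["i2", "rs2"], NA_real_)
  expect_equal(unclass(g)["i3", "rs1"], 2)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,rs1,rsX", "i1,0,2"), bad)
  expect_error(read_genotypes_csv(bad, panel), "not in panel")

  # .raw dialect: rs1 counted on the risk allele, rs2 on the other -> flip
  raw <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_T",
               "f1 i1 0 0 1 -9 2 0",
               "f2 i2 0 0 2 -9 1 2"), raw)
  gr <- read_genotypes_raw(raw, panel)
  expect_equal(unclass(gr)["i1", "rs1"], 2)
  expect_equal(unclass(gr)["i1", "rs2"], 2)  # flipped from 0
  expect_equal(unclass(gr)["i2", "rs2"], 0)

  # strand-ambiguous SNP is a hard error, never a guess
  amb_panel <- validate_snp_panel(data.frame(
    snp_id = "rs9", locus = "L9", risk_allele = "A", other_allele = "T",
    source_trait = "T2DM", stringsAsFactors = FALSE))
  raw2 <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs9_A",
               "f1 i1 0 0 1 -9 1"), raw2)
  expect_error(read_genotypes_raw(raw2, amb_panel), "strand-ambiguous")
})

test_that("VCF ingestion counts and orients risk alleles", {
  skip_if_not_installed("vcfR")
  panel <- validate_snp_panel(data.frame(
    snp_id = c("rs1", "rs2"), locus = c("L1", "L2"),
    risk_allele = c("A", "C"), other_allele = c("G", "T"),
    source_trait = "T2DM", stringsAsFactors = FALSE))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",   # ALT is risk
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t./."),  # REF is risk
    vcf)
  g <- read_genotypes_vcf(vcf, panel)
  expect_equal(unclass(g)["i1", "rs1"], 1)
  expect_equal(unclass(g)["i2", "rs1"], 2)
  expect_equal(unclass(g)["i1", "rs2"], 2)  # 0 ALT copies = 2 risk copies
  expect_true(is.na(unclass(g)["i2", "rs2"]))
})
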