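test_that("GWAS reader round-trips records and normalizes alleles", {
  path <- withr::local_tempfile(fileext = ".txt")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"),
                   A1 = c("a", "C", "g"), A2 = c("g", "T", "a"),
                   freq = c(0.30, 0.45, 0.12),
                   b = c(0.10, -0.05, 0.02), se = c(0.02, 0.01, 0.03),
                   p = c(5.7e-7, 5.9e-7, 0.50), n = c(1000, 1000, 1000))
  write_gwas_text(df, path)
  g <- read_gwas(path)
  expect_s3_class(g, "gwas_sumstats")
  expect_equal(nrow(g), 3)
  expect_equal(g$a1, c("A", "C", "G"))  # lowercase accepted, uppercased
  expect_equal(nrow(attr(g, "rejects")), 0)

  # write/read round trip preserves every field
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_gwas(g, path2)
  g2 <- read_gwas(path2)
  for (col in c("snp_id", "a1", "a2", "freq_a1", "beta", "se", "p", "n"))
    expect_equal(g2[[col]], g[[col]], info = col)
})

test_that("GWAS reader rejects invalid records without silent drops", {
  path <- withr::local_tempfile(fileext = ".txt")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   A1 = c("A", "A", "AT", "A", "A"),
                   A2 = c("G", "G", "G", "G", "A"),
                   freq = c(0.3, 0.3, 0.3, 0.3, 0.3),
                   b = c(0.1, 0.1, 0.1, NA, 0.1),
                   se = c(0.02, 0.02, 0.02, 0.02, 0.02),
                   p = c(0.5, 0, 0.5, 0.5, 0.5),
                   n = 100)
  write_gwas_text(df, path)
  g <- read_gwas(path)
  rej <- attr(g, "rejects")
  # p = 0, indel allele, missing beta, a1 == a2 all rejected with reasons
  expect_equal(nrow(g) + nrow(rej), 5)
  expect_setequal(rej$snp_id, c("rs2", "rs3", "rs4", "rs5"))
  expect_equal(rej$reason[rej$snp_id == "rs2"], "invalid_p")
  expect_equal(rej$reason[rej$snp_id == "rs3"], "invalid_allele")
  expect_equal(rej$reason[rej$snp_id == "rs4"], "missing_beta_se")
})

test_that("GWAS reader honours a column map and flags censored p-values", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id ea oa f beta stderr pval",
               "rs1 A G 0.3 0.1 0.02 <1.00E-300"), path)
  g <- read_gwas(path, column_map = c(SNP = "id", A1 = "ea", A2 = "oa",
                                      freq = "f", b = "beta", se = "stderr",
                                      p = "pval"))
  expect_equal(g$p, 1e-300)
  expect_true(g$p_censored)
  expect_error(read_gwas(path), "missing mandatory column")
})

test_that("eQTL reader groups by probe, dedups SNPs, handles empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(smrkit:::EQTL_COLUMNS, collapse = "\t")
  row <- function(pid, gene, ppos, snp, pos)
    paste(pid, gene, "1", ppos, snp, "1", pos, "A", "G",
          0.3, 0.1, 0.02, 1e-10, sep = "\t")
  lines <- c(hdr,
             sapply(1:5, function(i) row("p1", "G1", 500000, paste0("rs", i), 400000 + i)),
             sapply(1:5, function(i) row("p2", "G2", 800000, paste0("rs", i + 10), 700000 + i)))
  writeLines(lines, path)
  probes <- read_eqtl(path)
  expect_length(probes, 2)
  expect_equal(vapply(probes, function(p) nrow(p$snps), integer(1)),
               c(p1 = 5L, p2 = 5L))

  # duplicated snp_id: first kept, warning emitted
  writeLines(c(hdr, row("p1", "G1", 500000, "rs1", 400001),
               row("p1", "G1", 500000, "rs1", 400001)), path)
  expect_warning(probes <- read_eqtl(path), "duplicated")
  expect_equal(nrow(probes$p1$snps), 1)

  # conflicting probe_pos is a hard error
  writeLines(c(hdr, row("p1", "G1", 500000, "rs1", 400001),
               row("p1", "G1", 500009, "rs2", 400002)), path)
  expect_error(read_eqtl(path), "conflicting probe_pos")

  # header-only file: empty list, no error
  writeLines(hdr, path)
  expect_length(read_eqtl(path), 0)
})

test_that("eQTL writer/reader round-trip preserves probes", {
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 200,
                           n_gwas_cohort = 200, n_ref_panel = 50,
                           n_snps = 6, seed = 42)
  dat <- simulate_scenario(sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eqtl(dat$probes, path)
  back <- read_eqtl(path)
  expect_equal(back[[1]]$probe_pos, dat$probes[[1]]$probe_pos)
  expect_equal(back[[1]]$snps$beta, dat$probes[[1]]$snps$beta)
  expect_equal(back[[1]]$snps$se, dat$probes[[1]]$snps$se)
})

test_that("results writer round-trips values and writes NA for absent HEIDI", {
  res <- data.frame(probe_id = c("p1", "p2"), gene = c("G1", "G2"),
                    top_snp = c("rs1", NA), n_snps = c(10L, 0L),
                    b_smr = c(0.31234567, NA), se_smr = c(0.0412345, NA),
                    p_smr = c(3.2123456e-9, NA), p_heidi = c(NA, NA),
                    n_heidi_snps = c(2L, 0L),
                    passed_bonferroni = c(TRUE, NA), passed_heidi = c(NA, NA),
                    status = c("ok", "not_testable"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_true(grepl("\tNA\t", lines[2]))  # absent p_heidi printed as NA
  back <- read_results(path)
  expect_equal(back$b_smr[1], res$b_smr[1], tolerance = 1e-6)
  expect_equal(back$p_smr[1], res$p_smr[1], tolerance = 1e-6)
  expect_true(is.na(back$p_heidi[1]))
  expect_equal(back$passed_bonferroni, res$passed_bonferroni)

  # empty results: header-only file
  write_results(res[0, ], path)
  expect_length(readLines(path), 1)
  expect_error(write_results(NULL, path), "NULL")
})
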