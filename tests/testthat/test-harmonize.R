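test_that("align_alleles flips, matches, and rejects correctly", {
  # reversed orientation: beta negated, frequency reflected
  out <- align_alleles("A", "G", 0.10, 0.30, "G", "A")
  expect_equal(out$beta, -0.10)
  expect_equal(out$freq, 0.70)
  expect_true(out$flipped)
  # identical orientation: unchanged
  out <- align_alleles("A", "G", 0.10, 0.30, "A", "G")
  expect_equal(out$beta, 0.10)
  expect_equal(out$freq, 0.30)
  expect_false(out$flipped)
  # irreconcilable allele sets
  expect_null(align_alleles("A", "G", 0.10, 0.30, "A", "C"))
  # strand flip: T/C record against A/G target
  out <- align_alleles("T", "C", 0.10, 0.30, "A", "G")
  expect_equal(out$beta, 0.10)
  expect_true(out$strand_flipped)
})

test_that("double flip is the identity", {
  set.seed(4)
  for (i in 1:20) {
    beta <- rnorm(1); freq <- runif(1)
    once <- align_alleles("A", "G", beta, freq, "G", "A")
    twice <- align_alleles("G", "A", once$beta, once$freq, "A", "G")
    expect_equal(twice$beta, beta)
    expect_equal(twice$freq, freq)
  }
})

test_that("frequency check uses an inclusive boundary", {
  expect_true(frequency_check(0.30, 0.35, 0.2))
  expect_false(frequency_check(0.10, 0.45, 0.2))
  expect_true(frequency_check(0.5, 0.7, 0.2))   # boundary: <= passes
  expect_true(frequency_check(NA, 0.5, 0.2))    # nothing to compare
})

test_that("MAF filter drops below 0.01 in any source, strictly", {
  snps <- make_harmonized(paste0("rs", 1:3),
                          b_gwas = rep(0.1, 3), se_gwas = rep(0.02, 3),
                          b_eqtl = rep(0.5, 3), se_eqtl = rep(0.05, 3))
  snps$freq_gwas <- c(0.005, 0.01, 0.30)
  filt <- apply_snp_filters(snps, maf_min = 0.01)
  expect_equal(filt$dropped$snp_id, "rs1")        # 0.005 dropped
  expect_true("rs2" %in% filt$kept$snp_id)        # exactly 0.01 retained
  empty <- apply_snp_filters(snps[0, ], maf_min = 0.01)
  expect_equal(nrow(empty$kept), 0)
})

test_that("build_probe_dataset intersects sources inside the strict cis window", {
  set.seed(9)
  geno <- simulate_genotypes(400, 5, rep(0.3, 5), 0.5)
  panel <- make_panel(geno, snp_ids = paste0("rs", 1:5),
                      pos = c(200000L, 999999L, 1000000L, 1500000L, 2000000L))
  probe <- structure(list(
    probe_id = "p1", gene = "G1", chrom = "1", probe_pos = 0L,
    snps = data.frame(snp_id = paste0("rs", 1:5), chrom = "1",
                      pos = c(200000L, 999999L, 1000000L, 1500000L, 2000000L),
                      a1 = "A", a2 = "G", freq_a1 = 0.3,
                      beta = 0.5, se = 0.05, p = 1e-20, p_censored = FALSE,
                      stringsAsFactors = FALSE)), class = "eqtl_probe")
  gwas <- data.frame(snp_id = paste0("rs", c(1, 2, 3)), a1 = "A", a2 = "G",
                     freq_a1 = 0.3, beta = 0.1, se = 0.02, p = 1e-6,
                     p_censored = FALSE, n = 1000, stringsAsFactors = FALSE)
  class(gwas) <- c("gwas_sumstats", "data.frame")
  harm <- build_probe_dataset(probe, gwas, panel)
  # rs3 at exactly 1 Mb is excluded (strict <); rs4, rs5 outside; rs1, rs2 in
  expect_setequal(harm$snp_id, c("rs1", "rs2"))
  log <- attr(harm, "drop_log")
  expect_equal(sort(log$snp_id[log$reason == "outside_cis_window"]),
               c("rs3", "rs4", "rs5"))
  # exhaustive accounting: every probe SNP is kept or logged once
  expect_equal(nrow(harm) + nrow(log), nrow(probe$snps))
  expect_false(any(duplicated(log$snp_id)))
})

test_that("generator trio harmonizes losslessly and flips are invariant", {
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 1500,
                           n_gwas_cohort = 1500, n_ref_panel = 400,
                           n_snps = 10, seed = 31)
  dat <- simulate_scenario(sc)
  harm <- build_probe_dataset(dat$probes[[1]], dat$gwas, dat$panel)
  # consistent orientations: betas pass through unchanged
  idx <- match(harm$snp_id, dat$probes[[1]]$snps$snp_id)
  expect_equal(harm$b_eqtl, dat$probes[[1]]$snps$beta[idx])
  gidx <- match(harm$snp_id, dat$gwas$snp_id)
  expect_equal(harm$b_gwas, dat$gwas$beta[gidx])

  # orient every GWAS record the other way: a1/a2 swapped, beta negated,
  # freq reflected -> identical downstream SMR and HEIDI results
  flipped <- dat$gwas
  flipped$a1 <- dat$gwas$a2
  flipped$a2 <- dat$gwas$a1
  flipped$beta <- -dat$gwas$beta
  flipped$freq_a1 <- 1 - dat$gwas$freq_a1
  a1 <- smr_analysis(dat$gwas, dat$probes, dat$panel)
  a2 <- smr_analysis(flipped, dat$probes, dat$panel)
  expect_equal(a2$results$p_smr, a1$results$p_smr)
  expect_equal(a2$results$b_smr, a1$results$b_smr)
  expect_equal(a2$results$p_heidi, a1$results$p_heidi)
})

test_that("strand-ambiguous SNPs near 0.5 are dropped, others resolved", {
  set.seed(12)
  geno <- simulate_genotypes(500, 2, c(0.45, 0.15), 0)
  panel <- make_panel(geno, a1 = c("A", "C"), a2 = c("T", "G"),
                      pos = c(1000100L, 1000200L))
  probe <- structure(list(
    probe_id = "p1", gene = "G1", chrom = "1", probe_pos = 1000000L,
    snps = data.frame(snp_id = panel$variants$snp_id, chrom = "1",
                      pos = panel$variants$pos,
                      a1 = c("A", "C"), a2 = c("T", "G"),
                      freq_a1 = c(0.45, 0.15),
                      beta = 0.5, se = 0.05, p = 1e-20, p_censored = FALSE,
                      stringsAsFactors = FALSE)), class = "eqtl_probe")
  gwas <- data.frame(snp_id = panel$variants$snp_id, a1 = c("A", "C"),
                     a2 = c("T", "G"), freq_a1 = c(0.45, 0.15),
                     beta = 0.1, se = 0.02, p = 1e-6, p_censored = FALSE,
                     n = 1000, stringsAsFactors = FALSE)
  class(gwas) <- c("gwas_sumstats", "data.frame")
  harm <- build_probe_dataset(probe, gwas, panel)
  log <- attr(harm, "drop_log")
  # MAF 0.45 A/T: orientation undecidable, dropped; MAF 0.15 C/G resolved
  expect_true(panel$variants$snp_id[1] %in%
                log$snp_id[log$reason == "ambiguous_freq"])
  expect_true(panel$variants$snp_id[2] %in% harm$snp_id)
})
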