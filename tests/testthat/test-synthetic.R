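test_that("genotype simulation hits target MAFs and LD structure", {
  set.seed(61)
  mafs <- c(0.1, 0.25, 0.4)
  g <- simulate_genotypes(10000, 3, mafs, ld_rho = 0)
  emp <- colMeans(g) / 2
  # empirical MAF within 2 binomial SDs of target at n = 10,000
  sds <- sqrt(mafs * (1 - mafs) / (2 * 10000))
  expect_true(all(abs(emp - mafs) < 2 * sds + 1e-3))
  # rho = 0: off-diagonal dosage correlations near zero
  r <- cor(g)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  # rho = 0.9: adjacent dosage correlation strong but copula-attenuated
  g2 <- simulate_genotypes(10000, 5, rep(0.3, 5), ld_rho = 0.9)
  r_adj <- sapply(1:4, function(j) cor(g2[, j], g2[, j + 1]))
  expect_true(all(r_adj^2 > 0.35 & r_adj^2 < 0.9))
  # determinism under a fixed seed
  set.seed(99); ga <- simulate_genotypes(50, 4, 0.3, 0.5)
  set.seed(99); gb <- simulate_genotypes(50, 4, 0.3, 0.5)
  expect_identical(ga, gb)
})

test_that("phenotype models realize the generative effect structure", {
  set.seed(63)
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 50000,
                           n_gwas_cohort = 50000, n_snps = 5,
                           causal_index = 3, causal_index2 = 4, seed = 63)
  ge <- simulate_genotypes(50000, 5, rep(0.3, 5), 0.5)
  gg <- simulate_genotypes(50000, 5, rep(0.3, 5), 0.5)
  ph <- simulate_phenotypes(ge, gg, sc)
  # per-allele trait effect at the causal SNP is b_xy * b_zx = 0.15
  fit <- coef(lm(ph$trait ~ gg[, 3]))[2]
  expect_equal(unname(fit), 0.15, tolerance = 0.1)
  # expression responds only through the causal SNP
  fit_x <- coef(lm(ph$expression ~ ge[, 3]))[2]
  expect_equal(unname(fit_x), 0.5, tolerance = 0.05)

  # null expression effect: no SNP correlates with expression
  sc0 <- synthetic_scenario("null", b_zx = 0, n_snps = 5,
                            causal_index = 3, seed = 64)
  ph0 <- simulate_phenotypes(ge, gg, sc0)
  expect_lt(max(abs(cor(ge, ph0$expression))), 0.05)

  # linkage: trait associates with causal2, attenuated at causal1 by LD
  scl <- synthetic_scenario("linkage", n_snps = 5, causal_index = 3,
                            causal_index2 = 4, seed = 65)
  phl <- simulate_phenotypes(ge, gg, scl)
  b2 <- coef(lm(phl$trait ~ gg[, 4]))[2]
  b1 <- coef(lm(phl$trait ~ gg[, 3]))[2]
  expect_equal(unname(b2), scl$b_zy2, tolerance = 0.1)
  expect_lt(abs(b1), abs(b2))
  expect_gt(abs(b1), 0.01)  # LD leaks some signal to the neighbour
})

test_that("summarize_cohort matches a brute-force regression oracle", {
  set.seed(67)
  n <- 500
  g <- simulate_genotypes(n, 4, c(0.1, 0.2, 0.3, 0.4), 0.3)
  y <- 0.2 * g[, 2] + rnorm(n)
  fast <- summarize_cohort(g, y)
  for (j in 1:4) {
    fit <- summary(lm(y ~ g[, j]))$coefficients
    expect_equal(fast$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(fast$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(fast$p[j], fit[2, 4], tolerance = 1e-8)
  }
  # outcome identical to dosage: slope one, p at the floor
  ident <- summarize_cohort(g, as.numeric(g[, 1]))
  expect_equal(ident$beta[1], 1)
  expect_lt(ident$p[1], 1e-200)
  # monomorphic SNP flagged with undefined slope
  gm <- cbind(g, mono = 1L)
  sm <- summarize_cohort(gm, y)
  expect_true(sm$monomorphic[5])
  expect_true(is.na(sm$se[5]))
})

test_that("permuted outcomes give uniform association p-values", {
  set.seed(71)
  g <- simulate_genotypes(300, 200, runif(200, 0.1, 0.5), 0)
  y <- 0.3 * g[, 1] + rnorm(300)
  s <- summarize_cohort(g, sample(y))
  ks <- suppressWarnings(ks.test(s$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("written scenarios round-trip through the pipeline readers", {
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 400,
                           n_gwas_cohort = 400, n_ref_panel = 100,
                           n_snps = 8, seed = 73)
  dir1 <- withr::local_tempdir()
  paths <- write_scenario(sc, dir1)
  gwas <- read_gwas(paths$gwas)
  probes <- read_eqtl(paths$eqtl)
  panel <- read_plink(paths$panel)
  expect_equal(nrow(gwas), 8)
  expect_equal(nrow(attr(gwas, "rejects")), 0)
  expect_length(probes, 1)
  expect_equal(nrow(panel$variants), 8)
  # consistent orientations: nothing dropped except by chance-frequency rules
  harm <- build_probe_dataset(probes[[1]], gwas, panel)
  expect_equal(nrow(harm), 8)
  # manifest + seed reproduce byte-identical files
  dir2 <- withr::local_tempdir()
  manifest <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  sc2 <- synthetic_scenario(manifest$architecture,
                            n_eqtl_cohort = manifest$n_eqtl_cohort,
                            n_gwas_cohort = manifest$n_gwas_cohort,
                            n_ref_panel = manifest$n_ref_panel,
                            n_snps = manifest$n_snps,
                            maf_range = manifest$maf_range,
                            ld_rho = manifest$ld_rho, b_zx = manifest$b_zx,
                            b_xy = manifest$b_xy, b_zy2 = manifest$b_zy2,
                            causal_index = manifest$causal_index,
                            causal_index2 = manifest$causal_index2,
                            sd_x = manifest$sd_x, sd_y = manifest$sd_y,
                            seed = manifest$seed)
  paths2 <- write_scenario(sc2, dir2)
  for (f in c("gwas", "eqtl")) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }
  expect_identical(readBin(paste0(paths$panel, ".bed"), "raw", 10000),
                   readBin(paste0(paths2$panel, ".bed"), "raw", 10000))
})

test_that("generated summary data satisfy the SMR identity at the causal SNP", {
  # under pleiotropy, b_gwas ~ b_xy * b_eqtl at the causal SNP: the
  # discrepancy should lie within 2 combined standard errors most of the time
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 2000,
                           n_gwas_cohort = 2000, n_ref_panel = 100,
                           n_snps = 10, causal_index = 5, seed = 77)
  n_rep <- 200
  ok <- logical(n_rep)
  smrkit:::with_seed(sc$seed, {
    for (r in seq_len(n_rep)) {
      dat <- smrkit:::draw_scenario_data(sc, with_panel = FALSE)
      i <- sc$causal_index
      diff <- dat$gwas_sum$beta[i] - sc$b_xy * dat$eqtl_sum$beta[i]
      se <- sqrt(dat$gwas_sum$se[i]^2 + sc$b_xy^2 * dat$eqtl_sum$se[i]^2)
      ok[r] <- abs(diff) < 2 * se
    }
  })
  expect_gte(mean(ok), 0.90)
})

test_that("reference panel individuals are independent of the cohorts", {
  sc <- synthetic_scenario("pleiotropy", n_eqtl_cohort = 300,
                           n_gwas_cohort = 300, n_ref_panel = 300,
                           n_snps = 5, seed = 79)
  dat <- simulate_scenario(sc)
  # same LD model, different draws: LD estimates agree within sampling error
  r_panel <- ld_matrix(dat$panel, dat$panel$variants$snp_id)
  g_big <- smrkit:::with_seed(123,
    simulate_genotypes(20000, 5, dat$truth$mafs, sc$ld_rho))
  r_true <- cor(g_big)
  expect_lt(max(abs(r_panel - r_true)), 4 / sqrt(300))
})
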