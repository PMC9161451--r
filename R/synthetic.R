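# Synthetic-data generator. Emulates the three inputs of a summary-data MR
# analysis — an expression cohort, an independent trait cohort, and an
# individual-level reference panel — under explicit generative models:
#   pleiotropy: one variant drives expression, and expression drives the
#               trait (b_GWAS = b_xy * b_eQTL at the causal SNP);
#   linkage:    two distinct variants in LD, one driving expression and one
#               driving the trait directly;
#   null:       the variant drives expression only.
# LD follows an AR(1) Gaussian copula: latent haplotype values with
# correlation rho^|i-j| are thresholded at the MAF quantile and the two
# haplotypes summed to a dosage.

NONAMBIGUOUS_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                           c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Define a synthetic SMR scenario
#'
#' Bundles the generative-model parameters for one cis locus. Defaults
#' describe a well-powered brain-eQTL-style setting: cohorts of 5,000, a
#' 500-individual reference panel, 20 SNPs spaced 5 kb apart inside the cis
#' window, MAF drawn uniformly in (0.1, 0.5), AR(1) latent LD decay 0.85
#' (adjacent dosages correlate at roughly r = 0.6 after the copula
#' attenuation), a causal eQTL effect of 0.5 per allele, and an
#' expression-on-trait effect of 0.3 under pleiotropy. Under linkage the
#' two causal variants are adjacent, realizing LD of about r = 0.6.
#'
#' @param architecture `"pleiotropy"`, `"linkage"`, or `"null"`.
#' @param n_eqtl_cohort,n_gwas_cohort,n_ref_panel Cohort sizes.
#' @param n_snps Number of SNPs at the locus.
#' @param maf_range Range the per-SNP MAFs are drawn from.
#' @param ld_rho AR(1) decay of the latent haplotype correlation, in `[0, 1)`.
#' @param b_zx Causal-SNP effect on expression (per allele).
#' @param b_xy Expression effect on the trait (pleiotropy; ignored under
#'   linkage, forced 0 under null).
#' @param b_zy2 Direct effect of the second causal variant on the trait
#'   (linkage only).
#' @param causal_index Index of the expression causal SNP (default:
#'   mid-locus).
#' @param causal_index2 Index of the trait causal SNP under linkage (must
#'   differ from `causal_index`; default: adjacent to it).
#' @param sd_x,sd_y Residual standard deviations of expression and trait.
#' @param seed RNG seed.
#' @return A validated `smr_scenario` list.
#' @export
synthetic_scenario <- function(architecture = c("pleiotropy", "linkage", "null"),
                               n_eqtl_cohort = 5000, n_gwas_cohort = 5000,
                               n_ref_panel = 500, n_snps = 20,
                               maf_range = c(0.1, 0.5), ld_rho = 0.85,
                               b_zx = 0.5, b_xy = 0.3, b_zy2 = 0.3,
                               causal_index = NULL, causal_index2 = NULL,
                               sd_x = 1, sd_y = 1, seed = 1) {
  architecture <- match.arg(architecture)
  # default: causal variant mid-locus, second causal variant adjacent
  if (is.null(causal_index)) causal_index <- max(1L, ceiling(n_snps / 2))
  if (is.null(causal_index2))
    causal_index2 <- if (causal_index < n_snps) causal_index + 1L
                     else causal_index - 1L
  stopifnot(n_eqtl_cohort >= 2, n_gwas_cohort >= 2, n_ref_panel >= 2,
            n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1,
            causal_index >= 1, causal_index <= n_snps,
            sd_x > 0, sd_y > 0)
  if (architecture == "linkage") {
    stopifnot(causal_index2 >= 1, causal_index2 <= n_snps)
    if (causal_index2 == causal_index)
      stop("linkage architecture requires two distinct causal indices")
  }
  if (architecture == "null") b_xy <- 0
  structure(list(architecture = architecture,
                 n_eqtl_cohort = n_eqtl_cohort, n_gwas_cohort = n_gwas_cohort,
                 n_ref_panel = n_ref_panel, n_snps = n_snps,
                 maf_range = maf_range, ld_rho = ld_rho,
                 b_zx = b_zx, b_xy = b_xy, b_zy2 = b_zy2,
                 causal_index = causal_index, causal_index2 = causal_index2,
                 sd_x = sd_x, sd_y = sd_y, seed = as.integer(seed)),
            class = "smr_scenario")
}

#' Simulate genotype dosages under AR(1) latent LD
#'
#' Draws two latent standard-normal haplotype vectors per individual with
#' AR(1) correlation `rho^|i-j|` across SNPs, thresholds each at the MAF
#' quantile (carrier if the latent value falls below `qnorm(maf)`), and sums
#' the two haplotypes into an allele-1 dosage in {0, 1, 2}. The thresholding
#' attenuates the dosage correlation relative to the latent `rho`; the
#' attenuation is measured empirically in the test-suite, never assumed.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of SNPs.
#' @param mafs Per-SNP minor (allele-1) frequencies, recycled to `n_snps`.
#' @param ld_rho AR(1) decay parameter in `[0, 1)`.
#' @return Integer dosage matrix `n_individuals x n_snps`.
#' @export
simulate_genotypes <- function(n_individuals, n_snps, mafs, ld_rho = 0) {
  mafs <- rep_len(mafs, n_snps)
  stopifnot(all(mafs > 0), all(mafs < 1), ld_rho >= 0, ld_rho < 1)
  nh <- 2L * n_individuals
  Z <- matrix(stats::rnorm(nh * n_snps), nh, n_snps)
  if (ld_rho > 0 && n_snps > 1) {
    s <- sqrt(1 - ld_rho^2)
    for (j in 2:n_snps) Z[, j] <- ld_rho * Z[, j - 1] + s * Z[, j]
  }
  thr <- matrix(stats::qnorm(mafs), nh, n_snps, byrow = TRUE)
  carrier <- Z < thr
  g <- carrier[seq_len(n_individuals), , drop = FALSE] +
       carrier[n_individuals + seq_len(n_individuals), , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Simulate expression and trait phenotypes
#'
#' Expression in the eQTL cohort is `x = b_zx * g_causal + N(0, sd_x^2)`.
#' The trait in the independent GWAS cohort is, per architecture:
#' pleiotropy `y = b_xy * b_zx * g_causal + N(0, sd_y^2)` (the genetically
#' determined part of expression, mediated to the trait); linkage
#' `y = b_zy2 * g_causal2 + N(0, sd_y^2)`; null, pure noise.
#'
#' @param genotypes_eqtl Dosage matrix for the expression cohort.
#' @param genotypes_gwas Dosage matrix for the trait cohort.
#' @param scenario An `smr_scenario`.
#' @return List with `expression` and `trait` vectors.
#' @export
simulate_phenotypes <- function(genotypes_eqtl, genotypes_gwas, scenario) {
  stopifnot(inherits(scenario, "smr_scenario"))
  if (ncol(genotypes_eqtl) != scenario$n_snps ||
      ncol(genotypes_gwas) != scenario$n_snps)
    stop("genotype matrices do not match the scenario's n_snps")
  g1 <- genotypes_eqtl[, scenario$causal_index]
  x <- scenario$b_zx * g1 + stats::rnorm(nrow(genotypes_eqtl), 0, scenario$sd_x)
  noise_y <- stats::rnorm(nrow(genotypes_gwas), 0, scenario$sd_y)
  y <- switch(scenario$architecture,
    pleiotropy = scenario$b_xy * scenario$b_zx *
      genotypes_gwas[, scenario$causal_index] + noise_y,
    linkage = scenario$b_zy2 * genotypes_gwas[, scenario$causal_index2] + noise_y,
    null = noise_y)
  list(expression = x, trait = y)
}

#' Per-SNP least-squares association summary
#'
#' Regresses the outcome on each SNP dosage separately, returning the usual
#' summary-statistics columns: slope, its standard error, the two-sided
#' p-value from the t statistic, and the allele-1 frequency. Monomorphic
#' SNPs are flagged with undefined slope and SE.
#'
#' @param genotypes Dosage matrix (individuals x SNPs); `NA` allowed.
#' @param outcome Numeric outcome vector.
#' @return Data frame with `snp_id` (from column names, or `snp<j>`),
#'   `freq`, `beta`, `se`, `p`, `n_used`, `monomorphic`.
#' @export
summarize_cohort <- function(genotypes, outcome) {
  n <- nrow(genotypes)
  stopifnot(length(outcome) == n, n >= 3)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))

  if (!anyNA(genotypes) && !anyNA(outcome)) {
    gm <- colMeans(genotypes)
    Sxx <- colSums(genotypes^2) - n * gm^2
    ym <- mean(outcome)
    Sxy <- as.vector(crossprod(genotypes, outcome)) - n * gm * ym
    Syy <- sum(outcome^2) - n * ym^2
    mono <- Sxx <= 0
    beta <- ifelse(mono, NA_real_, Sxy / Sxx)
    sse <- pmax(Syy - beta * Sxy, 0)
    se <- ifelse(mono, NA_real_, sqrt(sse / ((n - 2) * Sxx)))
    tval <- beta / se
    p <- pmax(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
    p[mono] <- NA_real_
    return(data.frame(snp_id = ids, freq = gm / 2, beta = beta, se = se,
                      p = p, n_used = n, monomorphic = mono,
                      stringsAsFactors = FALSE))
  }

  rows <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    ok <- !is.na(g) & !is.na(outcome)
    g <- g[ok]; y <- outcome[ok]
    nj <- length(g)
    freq <- if (nj > 0) mean(g) / 2 else NA_real_
    if (nj < 3 || stats::var(g) == 0)
      return(data.frame(snp_id = ids[j], freq = freq, beta = NA_real_,
                        se = NA_real_, p = NA_real_, n_used = nj,
                        monomorphic = TRUE, stringsAsFactors = FALSE))
    fit <- summary(stats::lm(y ~ g))$coefficients
    data.frame(snp_id = ids[j], freq = freq, beta = fit["g", 1],
               se = fit["g", 2],
               p = max(fit["g", 4], .Machine$double.xmin),
               n_used = nj, monomorphic = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

# One realization of a scenario's locus layout (mafs, positions, alleles).
draw_locus <- function(scenario) {
  m <- scenario$n_snps
  mafs <- stats::runif(m, scenario$maf_range[1], scenario$maf_range[2])
  pair_idx <- sample.int(length(NONAMBIGUOUS_PAIRS), m, replace = TRUE)
  a1 <- vapply(NONAMBIGUOUS_PAIRS[pair_idx], `[`, character(1), 1)
  a2 <- vapply(NONAMBIGUOUS_PAIRS[pair_idx], `[`, character(1), 2)
  probe_pos <- 1000000L
  pos <- probe_pos - as.integer(floor(m / 2)) * 5000L + (seq_len(m) - 1L) * 5000L
  list(snp_id = sprintf("rs%06d", seq_len(m)), chrom = "1", pos = pos,
       a1 = a1, a2 = a2, mafs = mafs, probe_pos = probe_pos,
       probe_id = "probe_001", gene = "GENE1")
}

# Core single-draw machinery shared by simulate_scenario() and the
# replicate loops; assumes the RNG state is already positioned.
draw_scenario_data <- function(scenario, with_panel = TRUE) {
  loc <- draw_locus(scenario)
  g_e <- simulate_genotypes(scenario$n_eqtl_cohort, scenario$n_snps,
                            loc$mafs, scenario$ld_rho)
  g_g <- simulate_genotypes(scenario$n_gwas_cohort, scenario$n_snps,
                            loc$mafs, scenario$ld_rho)
  colnames(g_e) <- colnames(g_g) <- loc$snp_id
  ph <- simulate_phenotypes(g_e, g_g, scenario)
  eqtl_sum <- summarize_cohort(g_e, ph$expression)
  gwas_sum <- summarize_cohort(g_g, ph$trait)
  panel <- NULL
  if (with_panel) {
    g_p <- simulate_genotypes(scenario$n_ref_panel, scenario$n_snps,
                              loc$mafs, scenario$ld_rho)
    colnames(g_p) <- loc$snp_id
    rownames(g_p) <- sprintf("I%04d", seq_len(scenario$n_ref_panel))
    panel <- new_ref_panel(
      data.frame(snp_id = loc$snp_id, chrom = loc$chrom, pos = loc$pos,
                 a1 = loc$a1, a2 = loc$a2, stringsAsFactors = FALSE),
      g_p,
      data.frame(fid = sprintf("F%04d", seq_len(scenario$n_ref_panel)),
                 iid = sprintf("I%04d", seq_len(scenario$n_ref_panel)),
                 stringsAsFactors = FALSE))
  }
  list(locus = loc, eqtl_sum = eqtl_sum, gwas_sum = gwas_sum, panel = panel)
}

#' Simulate a complete in-memory SMR dataset
#'
#' Draws the locus (MAFs, positions, allele pairs), three independent
#' genotype samples (expression cohort, trait cohort, reference panel) from
#' the same LD model, the phenotypes, and the per-SNP summary statistics,
#' packaged in the containers the pipeline consumes. All three files/objects
#' are emitted in a mutually consistent allele orientation (allele-1 is the
#' counted allele everywhere); harmonization is exercised by deliberately
#' flipping records, which leaves results invariant.
#'
#' @param scenario An `smr_scenario`.
#' @return A list: `gwas` (`gwas_sumstats`), `probes` (list with one
#'   `eqtl_probe`), `panel` (`ref_panel`), `truth` (generative parameters
#'   and per-SNP true values).
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "smr_scenario"))
  with_seed(scenario$seed, {
    dat <- draw_scenario_data(scenario, with_panel = TRUE)
    loc <- dat$locus
    gwas <- data.frame(snp_id = loc$snp_id, a1 = loc$a1, a2 = loc$a2,
                       freq_a1 = dat$gwas_sum$freq, beta = dat$gwas_sum$beta,
                       se = dat$gwas_sum$se, p = dat$gwas_sum$p,
                       p_censored = FALSE,
                       n = as.numeric(scenario$n_gwas_cohort),
                       stringsAsFactors = FALSE)
    class(gwas) <- c("gwas_sumstats", "data.frame")
    snps <- data.frame(snp_id = loc$snp_id, chrom = loc$chrom, pos = loc$pos,
                       a1 = loc$a1, a2 = loc$a2,
                       freq_a1 = dat$eqtl_sum$freq, beta = dat$eqtl_sum$beta,
                       se = dat$eqtl_sum$se, p = dat$eqtl_sum$p,
                       p_censored = FALSE, stringsAsFactors = FALSE)
    probe <- structure(list(probe_id = loc$probe_id, gene = loc$gene,
                            chrom = loc$chrom, probe_pos = loc$probe_pos,
                            snps = snps),
                       class = "eqtl_probe")
    probes <- list(probe)
    names(probes) <- loc$probe_id
    truth <- list(scenario = scenario, mafs = loc$mafs,
                  causal_snp = loc$snp_id[scenario$causal_index],
                  causal_snp2 = if (scenario$architecture == "linkage")
                    loc$snp_id[scenario$causal_index2] else NA_character_,
                  b_xy = if (scenario$architecture == "pleiotropy")
                    scenario$b_xy else 0)
    list(gwas = gwas, probes = probes, panel = dat$panel, truth = truth)
  })
}

#' Write a synthetic scenario to disk
#'
#' Emits the GWAS summary text file, the eQTL TSV, the PLINK reference-panel
#' triplet, and a JSON manifest recording every generative parameter and the
#' seed, into `out_dir`. Re-running with the same scenario reproduces
#' byte-identical files.
#'
#' @param scenario An `smr_scenario`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of paths written.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- simulate_scenario(scenario)
  paths <- list(gwas = file.path(out_dir, "gwas.txt"),
                eqtl = file.path(out_dir, "eqtl.tsv"),
                panel = file.path(out_dir, "panel"),
                manifest = file.path(out_dir, "manifest.json"))
  write_gwas(dat$gwas, paths$gwas)
  write_eqtl(dat$probes, paths$eqtl)
  write_plink(dat$panel, paths$panel)
  manifest <- unclass(dat$truth$scenario)
  manifest$causal_snp <- dat$truth$causal_snp
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
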