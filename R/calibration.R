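# Replicate-level simulation helpers used for calibration, power, and
# parameter-recovery studies. Each replicate draws a fresh locus and fresh
# cohorts from the scenario's generative model; because the generator emits
# every dataset in a mutually consistent orientation, the harmonization
# bookkeeping reduces to assembling the joint per-SNP table directly, which
# keeps thousand-replicate studies fast. The full file-based path (including
# allele alignment) is exercised separately by the pipeline tests.

harmonized_from_draw <- function(dat) {
  loc <- dat$locus
  data.frame(snp_id = loc$snp_id, chrom = loc$chrom, pos = loc$pos,
             a1 = loc$a1, a2 = loc$a2,
             b_gwas = dat$gwas_sum$beta, se_gwas = dat$gwas_sum$se,
             p_gwas = dat$gwas_sum$p,
             b_eqtl = dat$eqtl_sum$beta, se_eqtl = dat$eqtl_sum$se,
             p_eqtl = dat$eqtl_sum$p, p_eqtl_censored = FALSE,
             freq_gwas = dat$gwas_sum$freq, freq_eqtl = dat$eqtl_sum$freq,
             freq_ref = if (is.null(dat$panel)) dat$eqtl_sum$freq else
               colMeans(dat$panel$genotypes) / 2,
             stringsAsFactors = FALSE)
}

#' Replicate SMR statistics under a scenario
#'
#' Runs `n_rep` independent replicates of the scenario, each drawing fresh
#' cohorts, selecting the top cis-eQTL SNP, and computing the SMR statistic.
#' Used for type-I-error calibration (null architecture) and parameter
#' recovery (pleiotropy).
#'
#' @param scenario An `smr_scenario` (its seed positions the RNG once).
#' @param n_rep Number of replicates.
#' @param p_eqtl_max Top-SNP eligibility threshold (default 5e-8).
#' @return Data frame with one row per replicate: `p_smr`, `b_smr`,
#'   `se_smr`, `t_smr` (`NA` when no SNP was eligible).
#' @export
replicate_smr <- function(scenario, n_rep, p_eqtl_max = 5e-8) {
  stopifnot(inherits(scenario, "smr_scenario"), n_rep >= 1)
  out <- data.frame(p_smr = rep(NA_real_, n_rep), b_smr = NA_real_,
                    se_smr = NA_real_, t_smr = NA_real_)
  with_seed(scenario$seed, {
    for (r in seq_len(n_rep)) {
      dat <- draw_scenario_data(scenario, with_panel = FALSE)
      harm <- harmonized_from_draw(dat)
      harm <- harm[!is.na(harm$p_eqtl), , drop = FALSE]
      top <- select_top_snp(harm, p_eqtl_max = p_eqtl_max)
      if (is.null(top)) next
      st <- smr_test(top)
      out$p_smr[r] <- st$p_smr
      out$b_smr[r] <- st$b_smr
      out$se_smr[r] <- st$se_smr
      out$t_smr[r] <- st$t_smr
    }
  })
  out
}

#' Replicate HEIDI tests under a scenario
#'
#' Runs `n_rep` independent replicates, each drawing fresh cohorts plus a
#' fresh reference panel, selecting the top SNP and the HEIDI instrument
#' set, and computing the HEIDI p-value. Used for null calibration
#' (pleiotropy architecture: a single shared causal variant IS the HEIDI
#' null) and for power against linkage.
#'
#' @param scenario An `smr_scenario`.
#' @param n_rep Number of replicates.
#' @param p_eqtl_max Top-SNP eligibility threshold.
#' @param r2_min,r2_max,p_eqtl_instrument_max,max_snps,min_snps HEIDI
#'   selection knobs (see [select_heidi_snps()] / [heidi_test()]).
#' @return Data frame with `p_heidi`, `t_heidi`, `n_snps_used` per
#'   replicate (`NA` when HEIDI could not be evaluated).
#' @export
replicate_heidi <- function(scenario, n_rep, p_eqtl_max = 5e-8,
                            r2_min = 0.05, r2_max = 0.90,
                            p_eqtl_instrument_max = 1.57e-3,
                            max_snps = 20, min_snps = 3) {
  stopifnot(inherits(scenario, "smr_scenario"), n_rep >= 1)
  out <- data.frame(p_heidi = rep(NA_real_, n_rep), t_heidi = NA_real_,
                    n_snps_used = NA_integer_)
  with_seed(scenario$seed, {
    for (r in seq_len(n_rep)) {
      dat <- draw_scenario_data(scenario, with_panel = TRUE)
      harm <- harmonized_from_draw(dat)
      harm <- harm[!is.na(harm$p_eqtl), , drop = FALSE]
      top <- select_top_snp(harm, p_eqtl_max = p_eqtl_max)
      if (is.null(top)) next
      hin <- select_heidi_snps(harm, top, dat$panel, r2_min = r2_min,
                               r2_max = r2_max,
                               p_eqtl_instrument_max = p_eqtl_instrument_max,
                               max_snps = max_snps)
      hres <- heidi_test(hin, min_snps = min_snps)
      out$p_heidi[r] <- hres$p_heidi
      out$t_heidi[r] <- hres$t_heidi
      out$n_snps_used[r] <- hres$n_snps_used
    }
  })
  out
}
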