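# The SMR instrumental-variable test. With independent GWAS and eQTL
# cohorts, the Wald ratio b_SMR = b_GWAS / b_eQTL estimates the effect of
# gene expression on the trait, and the chi-square(1) statistic
#   T_SMR = z2_GWAS * z2_eQTL / (z2_GWAS + z2_eQTL)
# combines the two squared z-scores (a harmonic-mean form: T_SMR is always
# bounded by the weaker of the two association signals).

#' Absolute z-score from a two-sided p-value
#'
#' Upper-tail standard-normal quantile at `p/2`, computed on the log scale
#' so that p-values down to the representable minimum (about 1e-300 and
#' below) convert without overflow. `z_from_p(1)` is 0.
#'
#' @param p Two-sided p-value(s) in `(0, 1]`.
#' @return `|z|` of the same length.
#' @export
z_from_p <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

squared_z <- function(beta, se, p) {
  if (!is.na(beta) && !is.na(se) && se > 0) (beta / se)^2 else z_from_p(p)^2
}

#' Select the top cis-eQTL SNP for a probe
#'
#' Returns the harmonized SNP with the smallest eQTL p-value, provided that
#' minimum is at or below `p_eqtl_max` (probes whose best cis-eQTL misses
#' genome-wide significance are not testable by SMR). Ties are broken by the
#' larger squared eQTL z-score, then by lexicographically smaller `snp_id`.
#'
#' @param snps Harmonized SNP data frame (see [build_probe_dataset()]).
#' @param p_eqtl_max Top-SNP eligibility threshold (default 5e-8, inclusive).
#' @return A one-row data frame, or `NULL` when no SNP is eligible.
#' @export
select_top_snp <- function(snps, p_eqtl_max = 5e-8) {
  if (is.null(snps) || nrow(snps) == 0) return(NULL)
  pmin_val <- min(snps$p_eqtl)
  if (pmin_val > p_eqtl_max) return(NULL)
  cand <- snps[snps$p_eqtl == pmin_val, , drop = FALSE]
  if (nrow(cand) > 1) {
    z2 <- mapply(squared_z, cand$b_eqtl, cand$se_eqtl, cand$p_eqtl)
    cand <- cand[order(-z2, cand$snp_id), , drop = FALSE]
  }
  cand[1, , drop = FALSE]
}

#' SMR test at the top instrument SNP
#'
#' Computes the squared z-scores for the GWAS and eQTL associations (from
#' beta/SE when both are available, otherwise from the p-value), the SMR
#' chi-square(1) statistic `T = z2_G * z2_E / (z2_G + z2_E)`, its upper-tail
#' p-value, the Wald ratio estimate `b_SMR = b_GWAS / b_eQTL`, and the
#' delta-method standard error
#' `|b_SMR| * sqrt(se_G^2/b_G^2 + se_E^2/b_E^2)`.
#'
#' @param top A one-row harmonized SNP data frame (or list with fields
#'   `snp_id`, `b_gwas`, `se_gwas`, `p_gwas`, `b_eqtl`, `se_eqtl`, `p_eqtl`).
#' @return An `smr_stat` list: `top_snp`, `z2_gwas`, `z2_eqtl`, `b_smr`,
#'   `se_smr`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(top) {
  z2_gwas <- squared_z(top$b_gwas, top$se_gwas, top$p_gwas)
  z2_eqtl <- squared_z(top$b_eqtl, top$se_eqtl, top$p_eqtl)
  if (z2_gwas + z2_eqtl == 0) {
    t_smr <- 0
    p_smr <- 1
  } else {
    t_smr <- z2_gwas * z2_eqtl / (z2_gwas + z2_eqtl)
    p_smr <- max(stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
                 .Machine$double.xmin)
  }
  have_betas <- !is.na(top$b_gwas) && !is.na(top$b_eqtl)
  b_smr <- if (have_betas && top$b_eqtl != 0) top$b_gwas / top$b_eqtl else NA_real_
  se_smr <- if (!is.na(b_smr) && top$b_gwas != 0 &&
                !is.na(top$se_gwas) && !is.na(top$se_eqtl))
    abs(b_smr) * sqrt(top$se_gwas^2 / top$b_gwas^2 +
                      top$se_eqtl^2 / top$b_eqtl^2)
  else NA_real_
  structure(list(top_snp = top$snp_id, z2_gwas = z2_gwas, z2_eqtl = z2_eqtl,
                 b_smr = b_smr, se_smr = se_smr, t_smr = t_smr, p_smr = p_smr),
            class = "smr_stat")
}

#' @export
print.smr_stat <- function(x, ...) {
  cat(sprintf("SMR at %s: b_smr = %.4g (se %.4g), T = %.3f, p = %.3e\n",
              x$top_snp, x$b_smr, x$se_smr, x$t_smr, x$p_smr))
  invisible(x)
}
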