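# HEIDI: heterogeneity in dependent instruments. Under a single shared
# causal variant (pleiotropy), the Wald ratio b_i = b_GWAS,i / b_eQTL,i is
# the same at every cis SNP in LD with the causal variant; under linkage
# (distinct causal variants) the ratios differ. HEIDI tests equality of the
# ratios at multiple correlated instruments against the top SNP's ratio.

#' Upper-tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k * chi2_1 > q)` for positive weights by Imhof's
#' numerical inversion of the characteristic function, falling back to a
#' Satterthwaite moment-matching approximation (scaled chi-square matching
#' the first two moments) when the integral fails to converge. The method
#' actually used is recorded in the `"method"` attribute. Because the
#' inversion integral resolves the tail only to absolute precision, results
#' below 1e-8 also defer to the moment-matching form, which is accurate on
#' the log scale in the far tail.
#'
#' @param q Observed quadratic-form value.
#' @param lambda Weights (eigenvalues); non-positive entries are dropped.
#' @param rel_tol Relative tolerance for the Imhof integral.
#' @return The tail probability, clamped to `(0, 1]`.
#' @export
wchisq_tail <- function(q, lambda, rel_tol = 1e-9) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0 || q <= 0) return(1)
  # one distinct weight: the distribution is an exact scaled chi-square
  if (max(lambda) - min(lambda) < 1e-12 * max(lambda)) {
    p <- min(max(stats::pchisq(q / lambda[1], df = length(lambda),
                               lower.tail = FALSE), .Machine$double.xmin), 1)
    attr(p, "method") <- "exact"
    return(p)
  }
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  satter <- min(max(stats::pchisq(q * s1 / s2, df = s1^2 / s2,
                                  lower.tail = FALSE),
                    .Machine$double.xmin), 1)
  # deep in the tail the inversion integral cannot resolve the probability
  # (it is additive around 1/2); go straight to the moment-matched form
  if (satter < 1e-9) {
    attr(satter, "method") <- "satterthwaite"
    return(satter)
  }
  # Imhof's inversion integral is oscillatory with an algebraically decaying
  # envelope; a single quadrature over (0, Inf) can misconverge, so the
  # integral is accumulated over geometrically growing finite segments until
  # the segment contributions vanish.
  imhof <- try({
    integrand <- function(u) {
      lu <- outer(lambda, u)
      theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(lu^2)))
      out <- sin(theta) / (u * rho)
      out[u == 0] <- 0.5 * (sum(lambda) - q)
      out
    }
    total <- 0
    lo <- 0; hi <- 1
    n_small <- 0L
    for (k in 1:64) {
      seg <- stats::integrate(integrand, lo, hi, rel.tol = rel_tol,
                              abs.tol = 1e-13, subdivisions = 500L,
                              stop.on.error = FALSE)
      total <- total + seg$value
      n_small <- if (abs(seg$value) < 1e-12) n_small + 1L else 0L
      if (n_small >= 2L && k > 4) break
      lo <- hi; hi <- 2 * hi
    }
    0.5 + total / pi
  }, silent = TRUE)
  if (!inherits(imhof, "try-error") && is.finite(imhof) &&
      imhof > 1e-8 && imhof < 1 + 1e-6) {
    p <- min(max(imhof, .Machine$double.xmin), 1)
    attr(p, "method") <- "imhof"
    return(p)
  }
  # Satterthwaite fallback: scale * chi2_df with matching mean and variance
  attr(satter, "method") <- "satterthwaite"
  satter
}

#' Select HEIDI instrument SNPs around a top SNP
#'
#' From the harmonized cis SNP set, keeps SNPs whose squared LD with the top
#' SNP lies in `[r2_min, r2_max]` (excluding near-duplicates of the top SNP
#' and SNPs carrying no shared signal) and whose eQTL p-value is below
#' `p_eqtl_instrument_max` (instruments must carry a real eQTL signal or the
#' ratio estimate is unstable). Remaining SNPs are then pairwise-pruned: for
#' any pair whose mutual r-squared falls outside the same window, the member
#' with the larger eQTL p-value is dropped. Finally, at most `max_snps`
#' SNPs with the smallest eQTL p-values are retained.
#'
#' @param snps Harmonized SNP data frame for the probe.
#' @param top One-row data frame: the top SNP from [select_top_snp()].
#' @param panel A `ref_panel` supplying the signed LD.
#' @param r2_min,r2_max LD window relative to the top SNP (defaults 0.05,
#'   0.90).
#' @param p_eqtl_instrument_max Instrument eQTL p threshold (default
#'   1.57e-3, i.e. |z| > 3.16).
#' @param max_snps Maximum number of non-top instruments (default 20).
#' @return A `heidi_input` list: `top`, `others`, `r_top` (signed r of each
#'   instrument with the top SNP), `r_mat` (signed r among top + instruments,
#'   top first).
#' @export
select_heidi_snps <- function(snps, top, panel, r2_min = 0.05, r2_max = 0.90,
                              p_eqtl_instrument_max = 1.57e-3, max_snps = 20) {
  others <- snps[snps$snp_id != top$snp_id, , drop = FALSE]
  if (nrow(others) > 0) {
    j <- match(c(top$snp_id, others$snp_id), panel$variants$snp_id)
    if (anyNA(j)) stop("SNP(s) not present in reference panel")
    r_all <- suppressWarnings(
      stats::cor(panel$genotypes[, j, drop = FALSE],
                 use = "pairwise.complete.obs"))
    r2 <- r_all[1, -1]^2
    keep <- !is.na(r2) & r2 >= r2_min & r2 <= r2_max &
      others$p_eqtl < p_eqtl_instrument_max
    others <- others[keep, , drop = FALSE]
    r_others <- r_all[-1, -1, drop = FALSE][keep, keep, drop = FALSE]
    # pairwise pruning among surviving instruments, strongest eQTL first:
    # a candidate enters only if its mutual r2 with every kept instrument
    # stays inside [r2_min, r2_max]
    if (nrow(others) > 1) {
      ord <- order(others$p_eqtl, others$snp_id)
      others <- others[ord, , drop = FALSE]
      rm_all <- r_others[ord, ord, drop = FALSE]
      kept <- integer(0)
      for (i in seq_len(nrow(others))) {
        r2i <- rm_all[i, kept]^2
        if (all(!is.na(r2i) & r2i >= r2_min & r2i <= r2_max))
          kept <- c(kept, i)
      }
      others <- others[kept, , drop = FALSE]
    }
  }
  if (nrow(others) > max_snps) {
    ord <- order(others$p_eqtl, others$snp_id)
    others <- others[ord[seq_len(max_snps)], , drop = FALSE]
  }
  ord <- order(others$pos, others$snp_id)
  others <- others[ord, , drop = FALSE]
  rownames(others) <- NULL

  ids <- c(top$snp_id, others$snp_id)
  r_mat <- if (length(ids) > 1) ld_matrix(panel, ids) else
    matrix(1, 1, 1, dimnames = list(ids, ids))
  structure(list(top = top, others = others,
                 r_top = r_mat[1, -1], r_mat = r_mat),
            class = "heidi_input")
}

# Delta-method covariance of Wald ratios b_i = bG_i / bE_i across SNPs i, j:
#   Cov(b_i, b_j) = r_ij seG_i seG_j / (bE_i bE_j)
#               + r_ij seE_i seE_j bG_i bG_j / (bE_i^2 bE_j^2)
# using Cov(bG_i, bG_j) = r_ij seG_i seG_j (same GWAS cohort), the analogous
# expression for the eQTL betas, and zero GWAS-eQTL cross-covariance
# (independent studies).
ratio_cov <- function(bG, seG, bE, seE, r_mat) {
  gw <- r_mat * outer(seG, seG) / outer(bE, bE)
  eq <- r_mat * outer(seE, seE) * outer(bG, bG) / outer(bE^2, bE^2)
  gw + eq
}

#' HEIDI heterogeneity test
#'
#' For each non-top instrument i, forms the difference of Wald ratios
#' `d_i = b_smr(i) - b_smr(top)`, its delta-method variance and
#' covariances (accounting for LD between instruments within each study and
#' independence across studies), standardizes to `z_d`, and refers
#' `T_HEIDI = sum z_d^2` to the null distribution `sum lambda_k chi2_1`
#' where `lambda_k` are the eigenvalues of the correlation matrix of `d`.
#' A small HEIDI p-value indicates heterogeneity among the ratios, i.e.
#' linkage rather than a single shared causal variant.
#'
#' @param input A `heidi_input` from [select_heidi_snps()].
#' @param min_snps Minimum number of non-top instruments required (default
#'   3); below this the p-value is reported absent (`NA`).
#' @param ridge Diagonal ridge added when the d-correlation matrix is
#'   numerically singular (default 1e-8; use is recorded in the result).
#' @return A `heidi_result` list: `t_heidi`, `df_effective`, `p_heidi`,
#'   `n_snps_used`, `method`, `ridged`.
#' @export
heidi_test <- function(input, min_snps = 3, ridge = 1e-8) {
  stopifnot(inherits(input, "heidi_input"))
  m <- nrow(input$others)
  if (m < min_snps)
    return(structure(list(t_heidi = NA_real_, df_effective = NA_real_,
                          p_heidi = NA_real_, n_snps_used = m,
                          method = NA_character_, ridged = FALSE),
                     class = "heidi_result"))
  all_snps <- rbind(input$top, input$others)
  bG <- all_snps$b_gwas; seG <- all_snps$se_gwas
  bE <- all_snps$b_eqtl; seE <- all_snps$se_eqtl
  if (any(bE == 0)) stop("HEIDI instrument with zero eQTL effect size")
  b_ratio <- bG / bE
  d <- b_ratio[-1] - b_ratio[1]

  cb <- ratio_cov(bG, seG, bE, seE, input$r_mat)
  # Cov(d_i, d_j) = Cov(b_i,b_j) - Cov(b_i,b_top) - Cov(b_j,b_top) + Var(b_top)
  V <- cb[-1, -1, drop = FALSE] -
    outer(cb[-1, 1], rep(1, m)) - outer(rep(1, m), cb[1, -1]) + cb[1, 1]
  sd_d <- sqrt(diag(V))
  z_d <- d / sd_d
  t_heidi <- sum(z_d^2)

  R <- V / outer(sd_d, sd_d)
  ridged <- FALSE
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    R <- R + diag(ridge, m)
    ridged <- TRUE
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  }
  lambda <- ev[ev > 1e-12]
  p <- wchisq_tail(t_heidi, lambda)
  structure(list(t_heidi = t_heidi,
                 df_effective = sum(lambda)^2 / sum(lambda^2),
                 p_heidi = as.numeric(p), n_snps_used = m,
                 method = attr(p, "method"), ridged = ridged),
            class = "heidi_result")
}

#' @export
print.heidi_result <- function(x, ...) {
  if (is.na(x$p_heidi))
    cat("HEIDI: not evaluated (", x$n_snps_used, " instruments)\n", sep = "")
  else
    cat(sprintf("HEIDI: T = %.3f over %d instruments, p = %.3e (%s)\n",
                x$t_heidi, x$n_snps_used, x$p_heidi, x$method))
  invisible(x)
}
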