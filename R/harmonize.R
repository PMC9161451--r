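# Allele harmonization: every dataset is oriented to the reference panel's
# allele-1 before any statistic is computed, so that b_gwas, b_eqtl, the
# frequencies, and the panel LD signs all refer to the same allele.

is_ambiguous_pair <- function(a1, a2) BASE_COMPLEMENT[a1] == a2

#' Orient one record's effect and frequency onto a target allele pair
#'
#' If the record's alleles match the target pair in reversed order the beta
#' is negated and the frequency reflected (`1 - freq`); a strand flip
#' (A<->T, C<->G complement) is attempted when the pairs do not match
#' directly. Irreconcilable allele sets return `NULL` (the SNP is dropped
#' upstream with reason `allele_mismatch`).
#'
#' @param a1,a2 The record's effect and other allele.
#' @param beta Effect size on the record's `a1`.
#' @param freq Frequency of the record's `a1` (may be `NA`).
#' @param target_a1,target_a2 Target orientation (usually the panel's).
#' @return A list `(beta, freq, flipped, strand_flipped)` or `NULL`.
#' @export
align_alleles <- function(a1, a2, beta, freq, target_a1, target_a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  target_a1 <- toupper(target_a1); target_a2 <- toupper(target_a2)
  match_pair <- function(x1, x2, strand_flipped) {
    if (x1 == target_a1 && x2 == target_a2)
      list(beta = beta, freq = freq, flipped = FALSE,
           strand_flipped = strand_flipped)
    else if (x1 == target_a2 && x2 == target_a1)
      list(beta = -beta, freq = if (is.na(freq)) NA_real_ else 1 - freq,
           flipped = TRUE, strand_flipped = strand_flipped)
    else NULL
  }
  out <- match_pair(a1, a2, FALSE)
  if (is.null(out) && a1 %in% VALID_BASES && a2 %in% VALID_BASES)
    out <- match_pair(unname(BASE_COMPLEMENT[a1]), unname(BASE_COMPLEMENT[a2]), TRUE)
  out
}

#' Effect-allele frequency concordance check
#'
#' Passes when the absolute frequency difference does not exceed `max_diff`
#' (boundary inclusive). Applied pairwise between GWAS, eQTL, and reference
#' panel frequencies; a failure drops the SNP with reason `freq_mismatch`.
#' `NA` frequencies pass (nothing to compare).
#'
#' @param freq_a,freq_b Allele-1 frequencies in `[0, 1]`.
#' @param max_diff Maximum tolerated absolute difference (default 0.2).
#' @export
frequency_check <- function(freq_a, freq_b, max_diff = 0.2) {
  if (is.na(freq_a) || is.na(freq_b)) return(TRUE)
  stopifnot(freq_a >= 0, freq_a <= 1, freq_b >= 0, freq_b <= 1)
  abs(freq_a - freq_b) <= max_diff
}

#' Minor-allele-frequency filter over harmonized SNPs
#'
#' Drops any SNP whose minor allele frequency (computed from the allele-1
#' frequency as `min(f, 1-f)`) is strictly below `maf_min` in ANY of the
#' three sources (GWAS, eQTL, reference panel).
#'
#' @param snps Harmonized SNP data frame (columns `freq_gwas`, `freq_eqtl`,
#'   `freq_ref`).
#' @param maf_min MAF threshold (default 0.01).
#' @return A list with the `kept` data frame and a `dropped` drop-log data
#'   frame (`snp_id`, `reason`).
#' @export
apply_snp_filters <- function(snps, maf_min = 0.01) {
  if (nrow(snps) == 0)
    return(list(kept = snps,
                dropped = data.frame(snp_id = character(), reason = character())))
  maf <- function(f) ifelse(is.na(f), Inf, pmin(f, 1 - f))
  low <- maf(snps$freq_gwas) < maf_min |
         maf(snps$freq_eqtl) < maf_min |
         maf(snps$freq_ref)  < maf_min
  list(kept = snps[!low, , drop = FALSE],
       dropped = data.frame(snp_id = snps$snp_id[low],
                            reason = rep("low_maf", sum(low)),
                            stringsAsFactors = FALSE))
}

empty_harmonized <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = integer(),
             a1 = character(), a2 = character(),
             b_gwas = numeric(), se_gwas = numeric(), p_gwas = numeric(),
             b_eqtl = numeric(), se_eqtl = numeric(), p_eqtl = numeric(),
             p_eqtl_censored = logical(),
             freq_gwas = numeric(), freq_eqtl = numeric(), freq_ref = numeric(),
             stringsAsFactors = FALSE)
}

# Orient a single record to the panel pair, resolving strand-ambiguous
# (A/T, C/G) pairs by frequency matching against the panel. Returns the
# aligned list, or a character drop reason.
orient_record <- function(a1, a2, beta, freq, t_a1, t_a2, freq_ref,
                          ambiguous_maf_max = 0.4) {
  if (is_ambiguous_pair(a1, a2)) {
    # orientation is undecidable from alleles alone: identity and
    # strand-flip+swap produce the same pair with opposite effect signs
    mafs <- c(freq, freq_ref)
    mafs <- mafs[!is.na(mafs)]
    if (length(mafs) > 0 && any(pmin(mafs, 1 - mafs) > ambiguous_maf_max))
      return("ambiguous_freq")
    asis <- align_alleles(a1, a2, beta, freq, t_a1, t_a2)
    if (is.null(asis)) return("allele_mismatch")
    if (is.na(freq) || is.na(freq_ref)) return(asis)  # assume same strand
    flip <- list(beta = -asis$beta, freq = 1 - asis$freq,
                 flipped = !asis$flipped, strand_flipped = TRUE)
    if (abs(asis$freq - freq_ref) <= abs(flip$freq - freq_ref)) asis else flip
  } else {
    out <- align_alleles(a1, a2, beta, freq, t_a1, t_a2)
    if (is.null(out)) "allele_mismatch" else out
  }
}

#' Build the analysis-ready harmonized SNP set for one probe
#'
#' Intersects a probe's cis-eQTL SNPs with the GWAS summary statistics and
#' the reference panel inside the cis window (strictly less than
#' `cis_window` bp from the probe position), orients all effects and
#' frequencies to the panel's allele-1, applies the effect-allele frequency
#' concordance check pairwise across the three sources, and removes SNPs
#' with minor allele frequency below `maf_min` in any source. GWAS records
#' without frequency information take their frequency from the reference
#' panel. Strand-ambiguous pairs are dropped when any source frequency is
#' within `1 - ambiguous_maf_max` of 0.5, otherwise resolved by frequency
#' matching.
#'
#' @param probe An `eqtl_probe`.
#' @param gwas A `gwas_sumstats` data frame.
#' @param panel A `ref_panel`.
#' @param cis_window Cis-window radius in bp (default 1e6; strict `<`).
#' @param maf_min Minimum minor allele frequency (default 0.01; strict `<`
#'   removal, matching "frequencies below 0.01 removed").
#' @param freq_diff_max Maximum allele-frequency discrepancy (default 0.2).
#' @param ambiguous_maf_max MAF above which A/T / C/G SNPs are considered
#'   unresolvable (default 0.4).
#' @return Harmonized data frame ordered by position then `snp_id`, with an
#'   exhaustive `"drop_log"` attribute (`snp_id`, `reason`).
#' @export
build_probe_dataset <- function(probe, gwas, panel, cis_window = 1e6,
                                maf_min = 0.01, freq_diff_max = 0.2,
                                ambiguous_maf_max = 0.4) {
  stopifnot(inherits(probe, "eqtl_probe"))
  snps <- probe$snps
  drop <- list()
  note <- function(ids, reason) {
    if (length(ids) > 0)
      drop[[length(drop) + 1]] <<- data.frame(snp_id = ids, reason = reason,
                                              stringsAsFactors = FALSE)
  }

  out_cis <- abs(snps$pos - probe$probe_pos) >= cis_window
  note(snps$snp_id[out_cis], "outside_cis_window")
  snps <- snps[!out_cis, , drop = FALSE]

  in_gwas <- snps$snp_id %in% gwas$snp_id
  note(snps$snp_id[!in_gwas], "not_in_gwas")
  snps <- snps[in_gwas, , drop = FALSE]

  in_panel <- snps$snp_id %in% panel$variants$snp_id
  note(snps$snp_id[!in_panel], "not_in_panel")
  snps <- snps[in_panel, , drop = FALSE]

  rows <- vector("list", nrow(snps))
  gw_idx <- match(snps$snp_id, gwas$snp_id)
  pv_idx <- match(snps$snp_id, panel$variants$snp_id)
  for (i in seq_len(nrow(snps))) {
    id <- snps$snp_id[i]
    t_a1 <- panel$variants$a1[pv_idx[i]]
    t_a2 <- panel$variants$a2[pv_idx[i]]
    g <- panel$genotypes[, pv_idx[i]]
    g <- g[!is.na(g)]
    if (length(g) == 0) { note(id, "panel_all_missing"); next }
    freq_ref <- mean(g) / 2

    eq <- orient_record(snps$a1[i], snps$a2[i], snps$beta[i], snps$freq_a1[i],
                        t_a1, t_a2, freq_ref, ambiguous_maf_max)
    if (is.character(eq)) { note(id, eq); next }
    gw <- gwas[gw_idx[i], ]
    ga <- orient_record(gw$a1, gw$a2, gw$beta, gw$freq_a1,
                        t_a1, t_a2, freq_ref, ambiguous_maf_max)
    if (is.character(ga)) { note(id, ga); next }

    freq_gwas <- if (is.na(ga$freq)) freq_ref else ga$freq
    ok <- frequency_check(freq_gwas, freq_ref, freq_diff_max) &&
          frequency_check(eq$freq, freq_ref, freq_diff_max) &&
          frequency_check(freq_gwas, eq$freq, freq_diff_max)
    if (!ok) { note(id, "freq_mismatch"); next }

    rows[[i]] <- data.frame(
      snp_id = id, chrom = snps$chrom[i], pos = snps$pos[i],
      a1 = t_a1, a2 = t_a2,
      b_gwas = ga$beta, se_gwas = gw$se, p_gwas = gw$p,
      b_eqtl = eq$beta, se_eqtl = snps$se[i], p_eqtl = snps$p[i],
      p_eqtl_censored = snps$p_censored[i],
      freq_gwas = freq_gwas, freq_eqtl = eq$freq, freq_ref = freq_ref,
      stringsAsFactors = FALSE)
  }
  harm <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                           list(make.row.names = FALSE)))
  if (is.null(harm)) harm <- empty_harmonized()

  filt <- apply_snp_filters(harm, maf_min = maf_min)
  harm <- filt$kept
  drop_log <- do.call(rbind, c(drop, list(make.row.names = FALSE)))
  if (is.null(drop_log))
    drop_log <- data.frame(snp_id = character(), reason = character())
  drop_log <- rbind(drop_log, filt$dropped)

  ord <- order(harm$pos, harm$snp_id)
  harm <- harm[ord, , drop = FALSE]
  rownames(harm) <- NULL
  attr(harm, "drop_log") <- drop_log
  harm
}
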