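# PLINK 1 binary genotype support. The .bed payload is SNP-major: per
# variant, ceiling(n/4) bytes, 2 bits per individual, low bits first.
# 2-bit codes: 00 = hom allele-1, 01 = missing, 10 = het, 11 = hom allele-2;
# we store dosages of the .bim allele-1 (0/1/2, NA for missing).

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_SNP_MAJOR <- as.raw(0x01)
BED_CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)      # index = code + 1
BED_DOSAGE_TO_CODE <- c(3L, 2L, 0L)                   # index = dosage + 1

#' Load a PLINK binary reference panel
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet into an individual-level genotype
#' panel. Genotypes are decoded to dosages of the `.bim` allele-1.
#'
#' @param prefix Common path prefix of the three files; alternatively give
#'   the three paths explicitly.
#' @param bed,bim,fam Explicit file paths (override `prefix`).
#' @return A `ref_panel` object: `variants` (data frame with `snp_id`,
#'   `chrom`, `pos`, `a1`, `a2`), `genotypes` (individuals x variants integer
#'   matrix of allele-1 dosages with `NA` for missing), `individuals`
#'   (data frame with `fid`, `iid`).
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed)) bed <- paste0(prefix, ".bed")
    if (is.null(bim)) bim <- paste0(prefix, ".bim")
    if (is.null(fam)) fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("panel file not found: ", f)

  bim_df <- data.table::fread(bim, header = FALSE, data.table = FALSE,
                              colClasses = list(character = c(1, 2, 5, 6)),
                              showProgress = FALSE)
  if (ncol(bim_df) < 6) stop("malformed .bim file: expected 6 columns")
  variants <- data.frame(snp_id = as.character(bim_df[[2]]),
                         chrom = as.character(bim_df[[1]]),
                         pos = as.integer(bim_df[[4]]),
                         a1 = toupper(bim_df[[5]]), a2 = toupper(bim_df[[6]]),
                         stringsAsFactors = FALSE)
  fam_df <- data.table::fread(fam, header = FALSE, data.table = FALSE,
                              colClasses = "character", showProgress = FALSE)
  individuals <- data.frame(fid = fam_df[[1]], iid = fam_df[[2]],
                            stringsAsFactors = FALSE)
  n_ind <- nrow(individuals)
  n_var <- nrow(variants)

  bytes <- readBin(bed, "raw", n = file.size(bed))
  if (length(bytes) < 3 || bytes[1] != PLINK_MAGIC[1] || bytes[2] != PLINK_MAGIC[2])
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (bytes[3] != PLINK_SNP_MAJOR)
    stop("only SNP-major .bed files (mode byte 0x01) are supported")
  bpv <- ceiling(n_ind / 4)
  if (length(bytes) - 3L != bpv * n_var)
    stop(".bed size inconsistent with .bim/.fam dimensions: expected ",
         bpv * n_var, " payload bytes, found ", length(bytes) - 3L)

  payload <- matrix(as.integer(bytes[-(1:3)]), nrow = bpv, ncol = n_var)
  geno <- matrix(NA_integer_, nrow = 4L * bpv, ncol = n_var)
  for (k in 0:3) {
    codes <- bitwAnd(bitwShiftR(payload, 2L * k), 3L)
    geno[seq(k + 1L, 4L * bpv, by = 4L), ] <-
      matrix(BED_CODE_TO_DOSAGE[codes + 1L], nrow = bpv)
  }
  geno <- geno[seq_len(n_ind), , drop = FALSE]
  colnames(geno) <- variants$snp_id
  rownames(geno) <- individuals$iid
  new_ref_panel(variants, geno, individuals)
}

new_ref_panel <- function(variants, genotypes, individuals) {
  stopifnot(nrow(genotypes) == nrow(individuals),
            ncol(genotypes) == nrow(variants))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be in {0, 1, 2, NA}")
  structure(list(variants = variants, genotypes = genotypes,
                 individuals = individuals),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel:", nrow(x$individuals), "individuals x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' Write a reference panel as a PLINK binary triplet
#'
#' @param panel A `ref_panel` object.
#' @param prefix Output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @export
write_plink <- function(panel, prefix) {
  geno <- panel$genotypes
  n_ind <- nrow(geno); n_var <- ncol(geno)
  bpv <- ceiling(n_ind / 4)
  # pad to a multiple of 4 individuals with code 0 (ignored on read)
  codes <- matrix(0L, nrow = 4L * bpv, ncol = n_var)
  g <- geno
  code_vals <- BED_DOSAGE_TO_CODE[g + 1L]
  code_vals[is.na(code_vals)] <- 1L
  codes[seq_len(n_ind), ] <- matrix(code_vals, nrow = n_ind)
  byte_mat <- codes[seq(1, 4L * bpv, by = 4L), , drop = FALSE] +
    4L  * codes[seq(2, 4L * bpv, by = 4L), , drop = FALSE] +
    16L * codes[seq(3, 4L * bpv, by = 4L), , drop = FALSE] +
    64L * codes[seq(4, 4L * bpv, by = 4L), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, PLINK_SNP_MAJOR), con)
  writeBin(as.raw(as.vector(byte_mat)), con)

  v <- panel$variants
  bim <- data.frame(v$chrom, v$snp_id, 0L, v$pos, v$a1, v$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$individuals$fid, panel$individuals$iid,
                    0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square goodness-of-fit comparing observed genotype counts to
#' Hardy-Weinberg expectations from the sample allele frequency. Monomorphic
#' variants return p = 1 by convention.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (allele-1 homozygote,
#'   heterozygote, allele-2 homozygote).
#' @return The HWE p-value.
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n <= 0) stop("total genotype count must be positive")
  p1 <- (2 * n_hom1 + n_het) / (2 * n)
  if (p1 <= 0 || p1 >= 1) return(1)  # monomorphic
  expected <- n * c(p1^2, 2 * p1 * (1 - p1), (1 - p1)^2)
  observed <- c(n_hom1, n_het, n_hom2)
  chisq <- sum((observed - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Allele-1 frequency of a panel variant
#'
#' Mean dosage over non-missing individuals divided by 2.
#'
#' @param panel A `ref_panel`.
#' @param snp_id Variant identifier.
#' @export
allele_freq <- function(panel, snp_id) {
  g <- panel_column(panel, snp_id)
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("allele frequency undefined: all genotypes missing for ", snp_id)
  mean(g) / 2
}

panel_column <- function(panel, snp_id) {
  j <- match(snp_id, panel$variants$snp_id)
  if (is.na(j)) stop("SNP not present in reference panel: ", snp_id)
  panel$genotypes[, j]
}

#' Signed LD correlation between two panel variants
#'
#' Pearson correlation of dosage columns over pairwise-complete individuals.
#' The sign refers to each variant's allele-1 orientation; squared it gives
#' the r-squared used for HEIDI instrument windows.
#'
#' @param panel A `ref_panel`.
#' @param snp_a,snp_b Variant identifiers.
#' @export
ld_r <- function(panel, snp_a, snp_b) {
  ga <- panel_column(panel, snp_a)
  gb <- panel_column(panel, snp_b)
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete individuals for LD")
  ga <- ga[ok]; gb <- gb[ok]
  if (stats::var(ga) == 0 || stats::var(gb) == 0)
    stop("LD undefined: zero genotype variance for ",
         if (stats::var(ga) == 0) snp_a else snp_b)
  stats::cor(ga, gb)
}

#' Signed LD matrix for a set of panel variants
#'
#' @param panel A `ref_panel`.
#' @param snp_ids Variant identifiers (order preserved in the output).
#' @return Symmetric matrix of pairwise dosage correlations.
#' @export
ld_matrix <- function(panel, snp_ids) {
  j <- match(snp_ids, panel$variants$snp_id)
  if (anyNA(j)) stop("SNP(s) not present in reference panel: ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  g <- panel$genotypes[, j, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  if (anyNA(r)) stop("LD undefined for some variant pair (zero variance or no overlap)")
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Reference-panel quality control
#'
#' Applies the standard panel QC in a fixed order: (1) remove variants with
#' call rate below `marker_call_rate`; (2) remove variants with minor allele
#' frequency below `maf_min`; (3) remove variants with Hardy-Weinberg
#' chi-square p below `hwe_p_max`; (4) remove individuals with call rate
#' (over the surviving variants) below `indiv_call_rate`. The fixed order
#' makes the per-step removal counts reproducible.
#'
#' @param panel A `ref_panel`.
#' @param marker_call_rate,maf_min,hwe_p_max,indiv_call_rate QC thresholds;
#'   defaults are per-marker call rate >= 0.95, MAF >= 0.05, HWE p >= 1e-6,
#'   per-individual call rate >= 0.95.
#' @return A list with the filtered `panel` and a `report` of class
#'   `panel_qc_report` carrying the per-step counts.
#' @export
qc_panel <- function(panel, marker_call_rate = 0.95, maf_min = 0.05,
                     hwe_p_max = 1e-6, indiv_call_rate = 0.95) {
  stopifnot(marker_call_rate >= 0, marker_call_rate <= 1,
            maf_min >= 0, maf_min <= 1,
            hwe_p_max >= 0, hwe_p_max <= 1,
            indiv_call_rate >= 0, indiv_call_rate <= 1)
  g <- panel$genotypes
  n_in <- ncol(g)

  call_rate <- colMeans(!is.na(g))
  fail_cr <- call_rate < marker_call_rate
  g1 <- g[, !fail_cr, drop = FALSE]

  freq <- colMeans(g1, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  maf <- pmin(freq, 1 - freq)
  fail_maf <- is.na(maf) | maf < maf_min
  g2 <- g1[, !fail_maf, drop = FALSE]

  hwe_p <- apply(g2, 2, function(col) {
    col <- col[!is.na(col)]
    hwe_test(sum(col == 2), sum(col == 1), sum(col == 0))
  })
  fail_hwe <- if (ncol(g2) > 0) hwe_p < hwe_p_max else logical(0)
  g3 <- g2[, !fail_hwe, drop = FALSE]

  ind_cr <- if (ncol(g3) > 0) rowMeans(!is.na(g3)) else rep(1, nrow(g3))
  fail_ind <- ind_cr < indiv_call_rate

  keep_var <- colnames(g3)
  keep_idx <- match(keep_var, panel$variants$snp_id)
  out_panel <- new_ref_panel(
    panel$variants[keep_idx, , drop = FALSE],
    g3[!fail_ind, , drop = FALSE],
    panel$individuals[!fail_ind, , drop = FALSE])

  report <- structure(list(
    n_variants_in = n_in,
    n_removed_call_rate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_individuals_removed = sum(fail_ind),
    n_variants_out = length(keep_var)
  ), class = "panel_qc_report")
  stopifnot(report$n_variants_out ==
              n_in - report$n_removed_call_rate - report$n_removed_maf -
              report$n_removed_hwe)
  list(panel = out_panel, report = report)
}

#' @export
print.panel_qc_report <- function(x, ...) {
  cat("Panel QC:", x$n_variants_in, "variants in,", x$n_variants_out, "out\n")
  cat("  removed: call rate", x$n_removed_call_rate,
      "| MAF", x$n_removed_maf, "| HWE", x$n_removed_hwe, "\n")
  cat("  individuals removed:", x$n_individuals_removed, "\n")
  invisible(x)
}
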