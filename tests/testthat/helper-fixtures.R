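# Fixtures built in code: tiny panels, consistent GWAS/eQTL/panel trios.

# A panel from an explicit dosage matrix (individuals x variants).
make_panel <- function(geno, snp_ids = NULL, a1 = NULL, a2 = NULL,
                       pos = NULL, chrom = "1") {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%06d", seq_len(m))
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  if (is.null(pos)) pos <- 1000000L + seq_len(m) * 1000L
  iid <- sprintf("I%03d", seq_len(n))
  dimnames(geno) <- list(iid, snp_ids)
  storage.mode(geno) <- "integer"
  smrkit:::new_ref_panel(
    data.frame(snp_id = snp_ids, chrom = chrom, pos = as.integer(pos),
               a1 = a1, a2 = a2, stringsAsFactors = FALSE),
    geno,
    data.frame(fid = sprintf("F%03d", seq_len(n)), iid = iid,
               stringsAsFactors = FALSE))
}

# A harmonized SNP data frame row-by-row from vectors.
make_harmonized <- function(snp_id, b_gwas, se_gwas, b_eqtl, se_eqtl,
                            p_gwas = NULL, p_eqtl = NULL, pos = NULL,
                            freq = 0.3) {
  m <- length(snp_id)
  if (is.null(p_gwas)) p_gwas <- 2 * pnorm(-abs(b_gwas / se_gwas))
  if (is.null(p_eqtl)) p_eqtl <- 2 * pnorm(-abs(b_eqtl / se_eqtl))
  if (is.null(pos)) pos <- 1000000L + seq_len(m) * 1000L
  data.frame(snp_id = snp_id, chrom = "1", pos = as.integer(pos),
             a1 = "A", a2 = "G",
             b_gwas = b_gwas, se_gwas = se_gwas, p_gwas = p_gwas,
             b_eqtl = b_eqtl, se_eqtl = se_eqtl, p_eqtl = p_eqtl,
             p_eqtl_censored = FALSE,
             freq_gwas = freq, freq_eqtl = freq, freq_ref = freq,
             stringsAsFactors = FALSE)
}

# Write a small GWAS summary file from a data.frame of standard columns.
write_gwas_text <- function(df, path) {
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  path
}
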