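#' @importFrom data.table fread
#' @importFrom stats pchisq pt qnorm rnorm runif cor setNames
#' @importFrom utils write.table
NULL

VALID_BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

GWAS_COLUMNS <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")

EQTL_COLUMNS <- c("probe_id", "gene", "probe_chrom", "probe_pos",
                  "snp_id", "snp_chrom", "snp_pos",
                  "a1", "a2", "freq_a1", "beta", "se", "p")

RESULT_COLUMNS <- c("probe_id", "gene", "top_snp", "n_snps",
                    "b_smr", "se_smr", "p_smr", "p_heidi", "n_heidi_snps",
                    "passed_bonferroni", "passed_heidi", "status")

# Parse p-value strings; censored entries like "<1.00E-300" are kept at the
# printed bound with a censoring flag (extreme associations are often
# reported that way in meta-analytic tables).
parse_pvalues <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, "<")
  x[censored] <- substring(x[censored], 2L)
  p <- suppressWarnings(as.numeric(x))
  list(p = p, censored = censored & !is.na(p))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Validate one batch of allele/statistic columns shared by the GWAS and eQTL
# readers. Returns a character vector of rejection reasons ("" = clean).
validate_sumstat_fields <- function(a1, a2, beta, se, p, freq) {
  reason <- character(length(a1))
  bad_allele <- !(a1 %in% VALID_BASES) | !(a2 %in% VALID_BASES) | a1 == a2
  reason[bad_allele] <- "invalid_allele"
  bad_bse <- reason == "" & (is.na(beta) | is.na(se))
  reason[bad_bse] <- "missing_beta_se"
  bad_se <- reason == "" & se <= 0
  reason[bad_se] <- "nonpositive_se"
  bad_p <- reason == "" & (is.na(p) | p <= 0 | p > 1)
  reason[bad_p] <- "invalid_p"
  bad_freq <- reason == "" & !is.na(freq) & (freq < 0 | freq > 1)
  reason[bad_freq] <- "invalid_freq"
  reason
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file in the common
#' `SNP A1 A2 freq b se p n` layout: per SNP, the effect allele (A1), the
#' other allele (A2), the effect-allele frequency, the per-allele effect on
#' the trait with its standard error, the two-sided association p-value, and
#' an optional sample size. Alleles are normalized to uppercase; only
#' single-base A/C/G/T alleles are accepted (the analysis is SNP-based).
#' Records failing validation are collected, never silently dropped, so that
#' input data lines = returned records + reported rejects.
#'
#' @param path Path to the summary-statistics file (mandatory header row).
#' @param column_map Optional named character vector mapping the standard
#'   names (`SNP`, `A1`, `A2`, `freq`, `b`, `se`, `p`, `n`) to the column
#'   names actually present in the file.
#' @return A `data.frame` of class `gwas_sumstats` with columns `snp_id`,
#'   `a1`, `a2`, `freq_a1`, `beta`, `se`, `p`, `p_censored`, `n`. Rejected
#'   records (with 1-based data-line numbers and reasons) are attached as
#'   attribute `"rejects"`.
#' @export
read_gwas <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("GWAS file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  cols <- GWAS_COLUMNS
  names(cols) <- GWAS_COLUMNS
  if (!is.null(column_map)) cols[names(column_map)] <- unname(column_map)
  mandatory <- setdiff(GWAS_COLUMNS, "n")
  missing_cols <- mandatory[!cols[mandatory] %in% names(raw)]
  if (length(missing_cols) > 0)
    stop("GWAS file is missing mandatory column(s): ",
         paste(cols[missing_cols], collapse = ", "))

  pp <- parse_pvalues(raw[[cols["p"]]])
  out <- data.frame(
    snp_id  = as.character(raw[[cols["SNP"]]]),
    a1      = toupper(trimws(raw[[cols["A1"]]])),
    a2      = toupper(trimws(raw[[cols["A2"]]])),
    freq_a1 = num_or_na(raw[[cols["freq"]]]),
    beta    = num_or_na(raw[[cols["b"]]]),
    se      = num_or_na(raw[[cols["se"]]]),
    p       = pp$p,
    p_censored = pp$censored,
    n = if (cols["n"] %in% names(raw)) num_or_na(raw[[cols["n"]]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  reason <- validate_sumstat_fields(out$a1, out$a2, out$beta, out$se,
                                    out$p, out$freq_a1)
  rejects <- data.frame(line = which(reason != ""),
                        snp_id = out$snp_id[reason != ""],
                        reason = reason[reason != ""],
                        stringsAsFactors = FALSE)
  out <- out[reason == "", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_sumstats", "data.frame")
  attr(out, "rejects") <- rejects
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_gwas()]: writes the standard `SNP A1 A2 freq b se p n`
#' layout, space-delimited, suitable for re-reading.
#'
#' @param gwas A `gwas_sumstats` data frame.
#' @param path Output path.
#' @export
write_gwas <- function(gwas, path) {
  out <- data.frame(SNP = gwas$snp_id, A1 = gwas$a1, A2 = gwas$a2,
                    freq = gwas$freq_a1, b = gwas$beta, se = gwas$se,
                    p = gwas$p, n = gwas$n)
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read cis-eQTL summary statistics
#'
#' Reads a tab-delimited file of per-gene-probe cis-eQTL associations with
#' columns `probe_id, gene, probe_chrom, probe_pos, snp_id, snp_chrom,
#' snp_pos, a1, a2, freq_a1, beta, se, p` and groups rows into one probe
#' object per `probe_id` (input order preserved). Duplicate SNP ids within a
#' probe keep the first occurrence with a warning; the same probe id with
#' conflicting probe positions is a hard error. The cis-window restriction is
#' applied downstream at harmonization time, not at load time.
#'
#' @param path Path to the eQTL TSV.
#' @return A list of `eqtl_probe` objects (fields `probe_id`, `gene`,
#'   `chrom`, `probe_pos`, `snps`), with record-level rejects attached as
#'   attribute `"rejects"`.
#' @export
read_eqtl <- function(path) {
  if (!file.exists(path)) stop("eQTL file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  missing_cols <- setdiff(EQTL_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("eQTL file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- list()
    attr(out, "rejects") <- data.frame(line = integer(), snp_id = character(),
                                       reason = character())
    return(out)
  }

  pp <- parse_pvalues(raw$p)
  snps <- data.frame(
    snp_id = as.character(raw$snp_id),
    chrom  = as.character(raw$snp_chrom),
    pos    = as.integer(num_or_na(raw$snp_pos)),
    a1     = toupper(trimws(raw$a1)),
    a2     = toupper(trimws(raw$a2)),
    freq_a1 = num_or_na(raw$freq_a1),
    beta   = num_or_na(raw$beta),
    se     = num_or_na(raw$se),
    p      = pp$p,
    p_censored = pp$censored,
    stringsAsFactors = FALSE
  )
  reason <- validate_sumstat_fields(snps$a1, snps$a2, snps$beta, snps$se,
                                    snps$p, snps$freq_a1)
  rejects <- data.frame(line = which(reason != ""),
                        snp_id = snps$snp_id[reason != ""],
                        reason = reason[reason != ""],
                        stringsAsFactors = FALSE)
  keep <- reason == ""
  snps <- snps[keep, , drop = FALSE]
  probe_id <- as.character(raw$probe_id)[keep]
  gene <- as.character(raw$gene)[keep]
  probe_chrom <- as.character(raw$probe_chrom)[keep]
  probe_pos <- as.integer(num_or_na(raw$probe_pos))[keep]

  probes <- list()
  for (pid in unique(probe_id)) {
    idx <- which(probe_id == pid)
    ppos <- unique(probe_pos[idx])
    if (length(ppos) != 1)
      stop("probe ", pid, " has conflicting probe_pos values: ",
           paste(ppos, collapse = ", "))
    psnps <- snps[idx, , drop = FALSE]
    dup <- duplicated(psnps$snp_id)
    if (any(dup)) {
      warning("probe ", pid, ": dropped duplicated snp_id(s): ",
              paste(unique(psnps$snp_id[dup]), collapse = ", "))
      psnps <- psnps[!dup, , drop = FALSE]
    }
    rownames(psnps) <- NULL
    probes[[pid]] <- structure(
      list(probe_id = pid, gene = gene[idx[1]], chrom = probe_chrom[idx[1]],
           probe_pos = ppos, snps = psnps),
      class = "eqtl_probe")
  }
  attr(probes, "rejects") <- rejects
  probes
}

#' Write cis-eQTL summary statistics
#'
#' Inverse of [read_eqtl()]: one row per probe/SNP pair in the TSV dialect.
#'
#' @param probes List of `eqtl_probe` objects.
#' @param path Output path.
#' @export
write_eqtl <- function(probes, path) {
  rows <- lapply(probes, function(pr) {
    data.frame(probe_id = pr$probe_id, gene = pr$gene,
               probe_chrom = pr$chrom, probe_pos = pr$probe_pos,
               snp_id = pr$snps$snp_id, snp_chrom = pr$snps$chrom,
               snp_pos = pr$snps$pos, a1 = pr$snps$a1, a2 = pr$snps$a2,
               freq_a1 = pr$snps$freq_a1, beta = pr$snps$beta,
               se = pr$snps$se, p = pr$snps$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- setNames(data.frame(matrix(nrow = 0, ncol = length(EQTL_COLUMNS))),
                    EQTL_COLUMNS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "e"))
  out
}

#' Write SMR/HEIDI results
#'
#' Writes the per-probe results table as TSV with a stable column order.
#' Floating-point columns are printed in scientific notation with 7
#' significant digits; absent values (e.g. `p_heidi` when too few HEIDI
#' instruments remained) are written as `NA`.
#'
#' @param results An `smr_results` data frame (see [smr_analysis()]).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  if (is.null(results)) stop("results must not be NULL")
  out <- data.frame(
    probe_id = as.character(results$probe_id),
    gene = as.character(results$gene),
    top_snp = as.character(results$top_snp),
    n_snps = as.integer(results$n_snps),
    b_smr = fmt_num(results$b_smr),
    se_smr = fmt_num(results$se_smr),
    p_smr = fmt_num(results$p_smr),
    p_heidi = fmt_num(results$p_heidi),
    n_heidi_snps = as.integer(results$n_heidi_snps),
    passed_bonferroni = results$passed_bonferroni,
    passed_heidi = results$passed_heidi,
    status = as.character(results$status),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return An `smr_results` data frame.
#' @export
read_results <- function(path) {
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  missing_cols <- setdiff(RESULT_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("results file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    probe_id = raw$probe_id, gene = raw$gene, top_snp = raw$top_snp,
    n_snps = as.integer(raw$n_snps),
    b_smr = num_or_na(raw$b_smr), se_smr = num_or_na(raw$se_smr),
    p_smr = num_or_na(raw$p_smr), p_heidi = num_or_na(raw$p_heidi),
    n_heidi_snps = as.integer(raw$n_heidi_snps),
    passed_bonferroni = as.logical(raw$passed_bonferroni),
    passed_heidi = as.logical(raw$passed_heidi),
    status = raw$status, stringsAsFactors = FALSE
  )
  class(out) <- c("smr_results", "data.frame")
  out
}
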