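# Orchestration: per probe, harmonize -> top-SNP SMR -> Bonferroni over the
# probes actually tested -> HEIDI only for Bonferroni survivors. HEIDI
# rejection means heterogeneity (linkage), so "survivors" are probes with
# p_heidi >= heidi_alpha.

#' Analysis configuration
#'
#' Collects file paths and thresholds for [run_analysis()]. All defaults are
#' the standard summary-data-MR settings: top-SNP eligibility p <= 5e-8,
#' MAF >= 0.01 in every source, allele-frequency concordance within 0.2,
#' HEIDI LD window r-squared in [0.05, 0.90], instrument eQTL p < 1.57e-3,
#' 3-20 instruments, and 0.05 significance levels for both the Bonferroni
#' gate and the HEIDI gate.
#'
#' @param gwas,eqtl Paths to the GWAS and eQTL summary files.
#' @param bfile Reference-panel PLINK prefix.
#' @param out_dir Output directory.
#' @param p_eqtl_max,maf_min,freq_diff_max,r2_min,r2_max,alpha,heidi_alpha
#'   Thresholds (see module functions).
#' @param heidi_min_snps,heidi_max_snps,heidi_instrument_p HEIDI knobs.
#' @param cis_window Cis-window radius in bp.
#' @param seed Optional integer seed recorded in the run report.
#' @return An `smr_config` list.
#' @export
smr_config <- function(gwas, eqtl, bfile, out_dir = NULL,
                       p_eqtl_max = 5e-8, maf_min = 0.01,
                       freq_diff_max = 0.2, r2_min = 0.05, r2_max = 0.90,
                       alpha = 0.05, heidi_alpha = 0.05,
                       heidi_min_snps = 3, heidi_max_snps = 20,
                       heidi_instrument_p = 1.57e-3,
                       cis_window = 1e6, seed = NULL) {
  thr <- c(p_eqtl_max = p_eqtl_max, maf_min = maf_min,
           freq_diff_max = freq_diff_max, r2_min = r2_min, r2_max = r2_max,
           alpha = alpha, heidi_alpha = heidi_alpha,
           heidi_instrument_p = heidi_instrument_p)
  if (any(thr <= 0 | thr >= 1))
    stop("all probability/frequency thresholds must lie strictly in (0, 1)")
  stopifnot(r2_min < r2_max, heidi_min_snps >= 1,
            heidi_max_snps >= heidi_min_snps, cis_window > 0)
  structure(list(gwas = gwas, eqtl = eqtl, bfile = bfile, out_dir = out_dir,
                 p_eqtl_max = p_eqtl_max, maf_min = maf_min,
                 freq_diff_max = freq_diff_max, r2_min = r2_min,
                 r2_max = r2_max, alpha = alpha, heidi_alpha = heidi_alpha,
                 heidi_min_snps = heidi_min_snps,
                 heidi_max_snps = heidi_max_snps,
                 heidi_instrument_p = heidi_instrument_p,
                 cis_window = cis_window, seed = seed),
            class = "smr_config")
}

#' Bonferroni significance threshold
#'
#' `alpha` divided by the number of gene probes with a valid SMR test.
#'
#' @param n_probes_tested Number of probes tested (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @export
bonferroni_threshold <- function(n_probes_tested, alpha = 0.05) {
  if (n_probes_tested < 1) stop("no probes were tested")
  alpha / n_probes_tested
}

default_opts <- function() smr_config(gwas = NULL, eqtl = NULL, bfile = NULL)

#' Run the SMR + HEIDI analysis on in-memory objects
#'
#' For every probe: build the harmonized cis SNP set, select the top eQTL
#' SNP, and compute the SMR statistic. Probes whose best cis-eQTL misses the
#' eligibility threshold are reported `not_testable` and do not consume
#' Bonferroni budget. The Bonferroni threshold is `alpha / n_probes_tested`;
#' HEIDI is evaluated only for Bonferroni survivors, which pass the
#' pleiotropy screen when `p_heidi >= heidi_alpha` (rejection = heterogeneity
#' = linkage).
#'
#' @param gwas A `gwas_sumstats` data frame.
#' @param probes List of `eqtl_probe` objects.
#' @param panel A `ref_panel`.
#' @param opts An `smr_config` (paths ignored); defaults used when `NULL`.
#' @return An `smr_analysis` list: `results` (an `smr_results` data frame),
#'   `report` (stage counts and the threshold used), `drop_log`, and
#'   `probe_data` (per-probe harmonized sets and HEIDI selections, for
#'   effect-pair export).
#' @export
smr_analysis <- function(gwas, probes, panel, opts = NULL) {
  if (is.null(opts)) opts <- default_opts()
  n_probes <- length(probes)
  if (n_probes == 0) stop("no probes supplied")

  rows <- vector("list", n_probes)
  probe_data <- list()
  drop_logs <- list()
  stats_list <- vector("list", n_probes)
  for (i in seq_len(n_probes)) {
    pr <- probes[[i]]
    harm <- build_probe_dataset(pr, gwas, panel,
                                cis_window = opts$cis_window,
                                maf_min = opts$maf_min,
                                freq_diff_max = opts$freq_diff_max)
    dl <- attr(harm, "drop_log")
    if (nrow(dl) > 0)
      drop_logs[[pr$probe_id]] <- data.frame(probe_id = pr$probe_id, dl,
                                             stringsAsFactors = FALSE)
    probe_data[[pr$probe_id]] <- list(harmonized = harm, heidi = NULL)
    base <- data.frame(probe_id = pr$probe_id, gene = pr$gene,
                       top_snp = NA_character_, n_snps = nrow(harm),
                       b_smr = NA_real_, se_smr = NA_real_, p_smr = NA_real_,
                       p_heidi = NA_real_, n_heidi_snps = 0L,
                       passed_bonferroni = NA, passed_heidi = NA,
                       status = "not_testable", stringsAsFactors = FALSE)
    if (nrow(harm) == 0) {
      base$status <- "no_snps"
      rows[[i]] <- base
      next
    }
    top <- select_top_snp(harm, p_eqtl_max = opts$p_eqtl_max)
    if (is.null(top)) {
      rows[[i]] <- base
      next
    }
    st <- smr_test(top)
    stats_list[[i]] <- st
    base$top_snp <- st$top_snp
    base$b_smr <- st$b_smr
    base$se_smr <- st$se_smr
    base$p_smr <- st$p_smr
    base$status <- "ok"
    probe_data[[pr$probe_id]]$top <- top
    rows[[i]] <- base
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  tested <- !is.na(results$p_smr)
  n_tested <- sum(tested)
  if (n_tested == 0) {
    report <- list(n_probes_in = n_probes, n_probes_tested = 0L,
                   error = "no testable probes")
    class(results) <- c("smr_results", "data.frame")
    return(structure(list(results = results, report = report,
                          drop_log = rbind_drop_logs(drop_logs),
                          probe_data = probe_data),
                     class = "smr_analysis"))
  }
  threshold <- bonferroni_threshold(n_tested, opts$alpha)
  results$passed_bonferroni[tested] <- results$p_smr[tested] < threshold

  n_heidi_run <- 0L
  for (i in which(tested & results$passed_bonferroni %in% TRUE)) {
    pid <- results$probe_id[i]
    hin <- select_heidi_snps(probe_data[[pid]]$harmonized,
                             probe_data[[pid]]$top, panel,
                             r2_min = opts$r2_min, r2_max = opts$r2_max,
                             p_eqtl_instrument_max = opts$heidi_instrument_p,
                             max_snps = opts$heidi_max_snps)
    hres <- heidi_test(hin, min_snps = opts$heidi_min_snps)
    probe_data[[pid]]$heidi <- hin
    n_heidi_run <- n_heidi_run + 1L
    results$n_heidi_snps[i] <- hres$n_snps_used
    results$p_heidi[i] <- hres$p_heidi
    if (!is.na(hres$p_heidi))
      results$passed_heidi[i] <- hres$p_heidi >= opts$heidi_alpha
  }

  report <- list(
    n_probes_in = n_probes,
    n_probes_with_snps = sum(results$status != "no_snps"),
    n_probes_tested = n_tested,
    alpha = opts$alpha,
    bonferroni_threshold = threshold,
    n_significant = sum(results$passed_bonferroni %in% TRUE),
    n_heidi_run = n_heidi_run,
    n_heidi_survivors = sum(results$passed_heidi %in% TRUE),
    heidi_alpha = opts$heidi_alpha,
    thresholds = list(p_eqtl_max = opts$p_eqtl_max, maf_min = opts$maf_min,
                      freq_diff_max = opts$freq_diff_max,
                      r2_min = opts$r2_min, r2_max = opts$r2_max,
                      heidi_min_snps = opts$heidi_min_snps,
                      heidi_max_snps = opts$heidi_max_snps,
                      heidi_instrument_p = opts$heidi_instrument_p,
                      cis_window = opts$cis_window),
    seed = opts$seed
  )
  class(results) <- c("smr_results", "data.frame")
  structure(list(results = results, report = report,
                 drop_log = rbind_drop_logs(drop_logs),
                 probe_data = probe_data),
            class = "smr_analysis")
}

rbind_drop_logs <- function(drop_logs) {
  out <- do.call(rbind, c(unname(drop_logs), list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(probe_id = character(), snp_id = character(),
                      reason = character())
  out
}

#' @export
print.smr_analysis <- function(x, ...) {
  r <- x$report
  cat("SMR analysis:", r$n_probes_in, "probes in,",
      r$n_probes_tested, "tested\n")
  if (!is.null(r$bonferroni_threshold))
    cat(sprintf("  Bonferroni threshold %.3e: %d significant, %d HEIDI survivors\n",
                r$bonferroni_threshold, r$n_significant, r$n_heidi_survivors))
  invisible(x)
}

#' Run the full file-based analysis
#'
#' Reads the GWAS summary file, the eQTL TSV, and the PLINK reference panel
#' named in the configuration, applies the standard panel QC, runs
#' [smr_analysis()], and writes to `out_dir`: `results.tsv`, `drop_log.tsv`,
#' `run_report.json`, and one effect-pair TSV per Bonferroni-significant
#' probe under `effect_pairs/`.
#'
#' @param config An `smr_config` with paths set.
#' @param panel_qc Apply [qc_panel()] to the panel first (default `TRUE`).
#' @return Invisibly, the `smr_analysis` object.
#' @export
run_analysis <- function(config, panel_qc = TRUE) {
  stopifnot(inherits(config, "smr_config"))
  gwas <- read_gwas(config$gwas)
  probes <- read_eqtl(config$eqtl)
  panel <- read_plink(config$bfile)
  qc_report <- NULL
  if (panel_qc) {
    qc <- qc_panel(panel)
    panel <- qc$panel
    qc_report <- unclass(qc$report)
  }
  ana <- smr_analysis(gwas, probes, panel, opts = config)
  ana$report$panel_qc <- qc_report

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(ana$results, file.path(config$out_dir, "results.tsv"))
    utils::write.table(ana$drop_log,
                       file.path(config$out_dir, "drop_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ana$report,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sig <- ana$results$probe_id[ana$results$passed_bonferroni %in% TRUE]
    if (length(sig) > 0) {
      ep_dir <- file.path(config$out_dir, "effect_pairs")
      dir.create(ep_dir, showWarnings = FALSE)
      for (pid in sig)
        export_effect_pairs(ana, pid, file.path(ep_dir, paste0(pid, ".tsv")))
    }
  }
  invisible(ana)
}

#' Export eQTL/GWAS effect-size pairs for one probe
#'
#' One row per SNP used in the probe's SMR/HEIDI evaluation, with both
#' harmonized effect sizes and flags marking the top SNP and the
#' HEIDI-selected subset — the data behind effect-size concordance plots
#' (GWAS effect against eQTL effect; their fitted slope has the sign of the
#' expression-on-trait effect).
#'
#' @param analysis An `smr_analysis` object.
#' @param probe_id Probe to export.
#' @param path Optional output TSV path.
#' @return The effect-pair data frame (invisibly when `path` is given).
#' @export
export_effect_pairs <- function(analysis, probe_id, path = NULL) {
  stopifnot(inherits(analysis, "smr_analysis"))
  pd <- analysis$probe_data[[probe_id]]
  if (is.null(pd)) stop("unknown probe: ", probe_id)
  harm <- pd$harmonized
  top_id <- if (!is.null(pd$top)) pd$top$snp_id else NA_character_
  heidi_ids <- if (!is.null(pd$heidi)) pd$heidi$others$snp_id else character(0)
  use <- harm$snp_id %in% c(top_id, heidi_ids)
  out <- data.frame(snp_id = harm$snp_id[use],
                    b_eqtl = harm$b_eqtl[use], se_eqtl = harm$se_eqtl[use],
                    b_gwas = harm$b_gwas[use], se_gwas = harm$se_gwas[use],
                    is_top = harm$snp_id[use] %in% top_id,
                    in_heidi_set = harm$snp_id[use] %in% heidi_ids,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
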