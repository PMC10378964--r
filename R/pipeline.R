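#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> QC -> kinship -> heritability -> GQLS scan +
#' chromosome-wise pFDR -> post-GWAS filter cascade -> replicated-forest
#' consensus -> GQLS/RF intersection -> LD blocks and SNP-to-gene mapping,
#' writing every report artifact into `out_dir` and returning a manifest.
#'
#' Report files: `cohort_summary.json` (case/control counts and
#' prevalence), `qc_report.json`, `h2_estimate.json`, `gqls_assoc.tsv`,
#' `manhattan.tsv` (-log10 q truncated at 6 with an exceedance flag),
#' `cascade_counts.json` + `cascade_snps.tsv`, `rf_consensus.tsv`,
#' `rf_errors.tsv`, `common_snps.tsv` (GQLS x RF), `gene_map.tsv`,
#' `ld_blocks.tsv`, plus the simulated inputs themselves, and
#' `manifest.json` with config, seed, per-stage row counts and md5 digests
#' of every artifact. All stages are deterministic given `config$seed`, so
#' re-running reproduces every digest.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param rf_forests,rf_trees forest protocol (defaults 100 x 75).
#' @param pfdr_tiers pFDR tier cutoffs.
#' @param maf_min,chi2_alpha,polarity_min cascade thresholds.
#' @param gene_window_bp SNP-to-gene window (default 2 Mb).
#' @param r2_min solid-spine / syntenic LD threshold (default 0.2).
#' @return invisibly, the manifest (list, also written as JSON).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         rf_forests = 100, rf_trees = 75,
                         pfdr_tiers = c(0.01, 0.05, 0.10),
                         maf_min = 0.2, chi2_alpha = 0.05,
                         polarity_min = 0.3,
                         gene_window_bp = 2e6, r2_min = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  t0 <- Sys.time()

  # --- simulate ----------------------------------------------------------
  bundle <- simulate_cohort(config)
  prefix <- file.path(out_dir, "cohort")
  write_cohort(bundle, prefix)
  counts$simulated_snps <- nrow(bundle$map)
  counts$phenotyped_animals <- length(bundle$phenotypes)

  cs <- cohort_summary(bundle$phenotypes)
  jsonlite::write_json(cs, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- QC ----------------------------------------------------------------
  qc <- qc_filter(bundle$genotypes)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
  g <- qc$genotypes
  counts$snps_after_qc <- ncol(g$dosage)
  counts$animals_after_qc <- nrow(g$dosage)
  status <- bundle$phenotypes[animal_ids(g)]

  # --- kinship + heritability -------------------------------------------
  K <- kinship_matrix(bundle$pedigree, g, method = "pedigree")
  h2 <- estimate_h2_pql_probit(status, K)
  jsonlite::write_json(
    list(h2_underlying = h2$h2_underlying, se_underlying = h2$se_underlying,
         h2_observed = h2$h2_observed, prevalence_alpha = h2$prevalence_alpha,
         sigma2_u = h2$sigma2_u, n_iter = h2$n_iter),
    file.path(out_dir, "h2_estimate.json"), auto_unbox = TRUE, digits = NA)

  # --- GQLS scan + pFDR --------------------------------------------------
  scan <- run_gwas(g, status, K = K)
  scan <- chromosome_pfdr(scan, tiers = pfdr_tiers)
  write.table(scan, file.path(out_dir, "gqls_assoc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manhattan_table(scan, file.path(out_dir, "manhattan.tsv"))
  sig <- scan[!is.na(scan$q_value) & scan$q_value <= max(pfdr_tiers), ,
              drop = FALSE]
  counts$gqls_significant <- nrow(sig)

  # --- post-GWAS cascade -------------------------------------------------
  cascade <- apply_cascade(sig, g, status, maf_min = maf_min,
                           chi2_alpha = chi2_alpha,
                           polarity_min = polarity_min)
  write_cascade_report(cascade, file.path(out_dir, "cascade_counts.json"))
  write.table(cascade$snp_table, file.path(out_dir, "cascade_snps.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  counts$cascade_survivors <- unname(cascade$survivors[["polarity"]])

  # --- replicated random forest -----------------------------------------
  g_train <- subset_genotypes(g, animals =
                                intersect(bundle$training_ids, animal_ids(g)))
  g_test <- subset_genotypes(g, animals =
                               intersect(bundle$testing_ids, animal_ids(g)))
  cons <- replicate_forests(g_train, status, n_forests = rf_forests,
                            n_trees = rf_trees, base_seed = config$seed)
  rec <- if (nrow(cons$records)) top_frequency_regions(cons) else
    cons$records
  write.table(rec, file.path(out_dir, "rf_consensus.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  errs <- evaluate_prediction(cons, g_test, status)
  write.table(cbind(set = rownames(errs), errs),
              file.path(out_dir, "rf_errors.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  counts$rf_retained <- nrow(cons$records)

  # polarity merged into the association table for the Table-8-style output
  sig2 <- merge(sig, cascade$snp_table[, c("snp_id", "polarity")],
                by = "snp_id", all.x = TRUE)
  common <- intersect_with_gqls(cons, sig2, q_max = max(pfdr_tiers))
  write.table(common, file.path(out_dir, "common_snps.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  counts$common_snps <- nrow(common)

  # --- LD blocks + gene mapping -----------------------------------------
  genes <- read_genes(paste0(prefix, "_genes.bed"), format = "bed")
  gm <- map_snps_to_genes(sig, genes, window_bp = gene_window_bp)
  write.table(gm, file.path(out_dir, "gene_map.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  counts$gene_mappings <- nrow(gm)

  blocks <- list()
  top_chr <- unique(sig$chromosome)
  for (chr in top_chr) {
    snps_chr <- sig$snp_id[sig$chromosome == chr]
    if (length(snps_chr) < 2) next
    reg <- subset_genotypes(g, snps = snps_chr)
    b <- solid_spine_blocks(reg, strong_ld_min = r2_min)
    if (nrow(b)) blocks[[length(blocks) + 1L]] <- b
  }
  btab <- if (length(blocks)) do.call(rbind, blocks) else
    solid_spine_blocks(subset_genotypes(g, snps = g$map$snp_id[1]),
                       strong_ld_min = r2_min)
  write.table(btab, file.path(out_dir, "ld_blocks.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  counts$ld_blocks <- nrow(btab)

  # --- manifest ----------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("spastigen")),
    seed = config$seed,
    config = unclass(config),
    thresholds = list(pfdr_tiers = pfdr_tiers, maf_min = maf_min,
                      chi2_alpha = chi2_alpha, polarity_min = polarity_min,
                      gene_window_bp = gene_window_bp, r2_min = r2_min,
                      rf_forests = rf_forests, rf_trees = rf_trees),
    stage_counts = counts,
    files = digests,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
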