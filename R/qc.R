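#' Pre-GWAS quality control
#'
#' Applies the pipeline's fixed-order screens to a genotype matrix:
#' \enumerate{
#'   \item drop animals with call rate below `ind_call_rate`;
#'   \item drop SNPs with call rate below `snp_call_rate` (computed on the
#'     remaining animals);
#'   \item drop SNPs whose heterozygosity excess — observed heterozygote
#'     frequency minus the Hardy-Weinberg expectation `2p(1-p)`, both on
#'     non-missing calls — is at least `het_excess_max`;
#'   \item drop SNPs with minor allele frequency at or below `maf_min`
#'     (monomorphic SNPs always drop here).
#' }
#' Each removed animal/SNP is attributed to exactly one filter (the first
#' that catches it), so the per-filter counts always reconcile with the
#' input and output dimensions. The screens are idempotent — re-running QC
#' on its own output removes nothing — unless an animal's call rate
#' straddles the threshold between the original and the surviving SNP
#' subset (possible under heavy missingness).
#'
#' @param g a [genotype_matrix()].
#' @param ind_call_rate,snp_call_rate minimum call rates (default 0.90).
#' @param het_excess_max exclusion threshold on heterozygosity excess
#'   (default 0.499).
#' @param maf_min exclusive MAF floor: SNPs with MAF <= `maf_min` drop
#'   (default 1e-5, a screen that keeps all but monomorphic and
#'   near-monomorphic markers).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`).
#' @export
qc_filter <- function(g, ind_call_rate = 0.90, snp_call_rate = 0.90,
                      het_excess_max = 0.499, maf_min = 0.00001) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(ind_call_rate = ind_call_rate, snp_call_rate = snp_call_rate,
           het_excess_max = het_excess_max, maf_min = maf_min)
  if (any(thr < 0 | thr > 1)) {
    bad <- names(thr)[thr < 0 | thr > 1]
    stop("threshold(s) outside [0,1]: ", paste(bad, collapse = ", "))
  }
  d <- g$dosage
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  n_animals_in <- nrow(d)
  n_snps_in <- ncol(d)

  # 1. individual call rate
  icr <- rowMeans(!is.na(d))
  drop_ind <- icr < ind_call_rate
  d <- d[!drop_ind, , drop = FALSE]

  # 2. SNP call rate
  scr <- colMeans(!is.na(d))
  drop_cr <- scr < snp_call_rate

  # 3. heterozygosity excess (on SNPs surviving 2)
  p <- colMeans(d, na.rm = TRUE) / 2
  h_obs <- colMeans(d == 1L, na.rm = TRUE)
  h_exp <- 2 * p * (1 - p)
  het_excess <- h_obs - h_exp
  drop_het <- !drop_cr & !is.na(het_excess) & het_excess >= het_excess_max

  # 4. MAF
  maf <- pmin(p, 1 - p)
  drop_maf <- !drop_cr & !drop_het & (is.na(maf) | maf <= maf_min)

  keep <- !(drop_cr | drop_het | drop_maf)
  out <- subset_genotypes(
    structure(list(dosage = d, map = g$map), class = "genotype_matrix"),
    snps = which(keep)
  )
  report <- structure(list(
    n_animals_in = n_animals_in,
    n_animals_out = nrow(out$dosage),
    n_snps_in = n_snps_in,
    n_snps_out = ncol(out$dosage),
    removed = c(
      individual_call_rate = sum(drop_ind),
      snp_call_rate = sum(drop_cr),
      heterozygosity_excess = sum(drop_het),
      maf = sum(drop_maf)
    ),
    thresholds = as.list(thr)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  animals: %d -> %d (individual call rate < %.2f: %d)\n",
              x$n_animals_in, x$n_animals_out, x$thresholds$ind_call_rate,
              x$removed[["individual_call_rate"]]))
  cat(sprintf("  SNPs:    %d -> %d\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("    call rate < %.2f:        %d\n",
              x$thresholds$snp_call_rate, x$removed[["snp_call_rate"]]))
  cat(sprintf("    het excess >= %.3f:     %d\n",
              x$thresholds$het_excess_max,
              x$removed[["heterozygosity_excess"]]))
  cat(sprintf("    MAF <= %g:           %d\n",
              x$thresholds$maf_min, x$removed[["maf"]]))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
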