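#' Minor allele frequency of one dosage column
#'
#' @param dose integer dosage vector (0/1/2, `NA` = missing).
#' @return `min(p, 1-p)` of the counted allele over non-missing calls.
#' @export
compute_maf <- function(dose) {
  dose <- dose[!is.na(dose)]
  if (!length(dose)) stop("undefined MAF: all calls missing")
  p <- mean(dose) / 2
  min(p, 1 - p)
}

#' Genotype-by-status chi-square test
#'
#' Pearson chi-square (no continuity correction) on the 2 (status) x k
#' (genotype class) table of non-missing calls, `k <= 3`; genotype classes
#' absent from the whole cohort are dropped, so df = k - 1. No minimum
#' expected-count rule is enforced; a warning notes small expected counts.
#'
#' @param dose dosage vector.
#' @param status 0/1 status vector, positionally aligned with `dose`.
#' @return list with `chi2`, `df`, `p_value`, `single_class` (TRUE when
#'   only one genotype class remains, in which case p = 1).
#' @export
chisq_genotype_test <- function(dose, status) {
  if (length(unique(status[!is.na(dose)])) < 2L) {
    stop("cohort error: both phenotype classes required")
  }
  keep <- !is.na(dose)
  tab <- table(factor(status[keep], levels = c(0, 1)),
               factor(dose[keep], levels = 0:2))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) {
    return(list(chi2 = 0, df = 0L, p_value = 1, single_class = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("chi-square table has expected counts < 5", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), single_class = FALSE)
}

#' Homozygotic polarity score
#'
#' Within each phenotype class, the proportions of the two homozygous
#' genotypes are computed over all non-missing animals of the class,
#' `p_hom0` and `p_hom2`; the class difference is `d = p_hom0 - p_hom2`
#' and the score is `|d_case - d_control|`, in `[0, 2]`. Large scores flag
#' SNPs whose two homozygous states are enriched in opposite disease
#' classes. When one homozygous genotype is absent from the entire cohort
#' there is only one homozygotic state to compare and the score is
#' undefined (`NA`).
#'
#' @param dose dosage vector.
#' @param status aligned 0/1 status vector.
#' @return the score, or `NA_real_` when only one homozygous class exists
#'   cohort-wide.
#' @export
polarity_score <- function(dose, status) {
  if (length(unique(status[!is.na(dose)])) < 2L) {
    stop("cohort error: both phenotype classes required")
  }
  keep <- !is.na(dose)
  d <- dose[keep]; s <- status[keep]
  if (!any(d == 0L) || !any(d == 2L)) return(NA_real_)
  dd <- function(cls) {
    dc <- d[s == cls]
    mean(dc == 0L) - mean(dc == 2L)
  }
  abs(dd(1) - dd(0))
}

#' Post-GWAS filter cascade
#'
#' Applies the post-GWAS screens cumulatively, in fixed order, to the SNPs
#' of an association scan (intended input: the SNPs significant at
#' chromosome-wise pFDR <= 10%):
#' \enumerate{
#'   \item MAF >= `maf_min` (default 0.2 — with case prevalence near 60%,
#'     disease-contributing alleles are expected to be common);
#'   \item genotype-by-status chi-square p < `chi2_alpha` (default 0.05);
#'   \item homozygotic polarity score >= `polarity_min` (default 0.3).
#' }
#' An undefined (NA) polarity score never passes the polarity stage but the
#' SNP is retained in the per-SNP table with its score marked N/A.
#'
#' @param records data.frame with at least `snp_id` (and `chromosome` for
#'   the per-chromosome summary), e.g. a tier-filtered `gqls_scan`.
#' @param g a [genotype_matrix()] containing the SNPs of `records`.
#' @param status named 0/1 vector over `animal_ids(g)`.
#' @param maf_min,chi2_alpha,polarity_min stage thresholds.
#' @return object of class `filter_cascade_report`: list with `snp_table`
#'   (per-SNP maf/chi2_p/polarity and pass flags), `survivors` (named
#'   cumulative counts per stage), `by_chromosome` (rows = chromosome,
#'   columns = stage, cumulative survivor counts), `thresholds`.
#' @export
apply_cascade <- function(records, g, status, maf_min = 0.2,
                          chi2_alpha = 0.05, polarity_min = 0.3) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (chi2_alpha < 0 || chi2_alpha > 1) stop("chi2_alpha must be in [0,1]")
  if (polarity_min < 0 || polarity_min > 2) {
    stop("polarity_min must be in [0,2]")
  }
  stages <- c("input", "maf", "chi_square", "polarity")
  x <- as.numeric(status[animal_ids(g)])
  n <- nrow(records)
  if (n == 0L) {
    rep0 <- structure(list(
      snp_table = data.frame(snp_id = character(), chromosome = integer(),
                             maf = numeric(), chi2_p = numeric(),
                             polarity = numeric(), pass_maf = logical(),
                             pass_chi2 = logical(), pass_polarity = logical()),
      survivors = setNames(rep(0L, 4L), stages),
      by_chromosome = NULL,
      thresholds = list(maf_min = maf_min, chi2_alpha = chi2_alpha,
                        polarity_min = polarity_min)
    ), class = "filter_cascade_report")
    return(rep0)
  }
  idx <- match(records$snp_id, g$map$snp_id)
  if (anyNA(idx)) {
    stop("SNP(s) in records absent from genotypes: ",
         paste(utils::head(records$snp_id[is.na(idx)], 5), collapse = ", "))
  }
  maf <- numeric(n); chi2p <- numeric(n); pol <- numeric(n)
  for (i in seq_len(n)) {
    dj <- g$dosage[, idx[i]]
    maf[i] <- compute_maf(dj)
    chi2p[i] <- chisq_genotype_test(dj, x)$p_value
    pol[i] <- polarity_score(dj, x)
  }
  pass_maf <- maf >= maf_min
  pass_chi2 <- pass_maf & (chi2p < chi2_alpha | chi2_alpha >= 1)
  pass_pol <- pass_chi2 & !is.na(pol) & pol >= polarity_min

  chrom <- if ("chromosome" %in% names(records)) records$chromosome
           else g$map$chromosome[idx]
  snp_table <- data.frame(
    snp_id = records$snp_id, chromosome = chrom,
    maf = maf, chi2_p = chi2p, polarity = pol,
    pass_maf = pass_maf, pass_chi2 = pass_chi2, pass_polarity = pass_pol,
    stringsAsFactors = FALSE
  )
  cum <- cbind(input = TRUE, maf = pass_maf, chi_square = pass_chi2,
               polarity = pass_pol)
  by_chr <- do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
    colSums(cum[chrom == ch, , drop = FALSE])
  }))
  rownames(by_chr) <- sort(unique(chrom))
  structure(list(
    snp_table = snp_table,
    survivors = colSums(cum),
    by_chromosome = by_chr,
    thresholds = list(maf_min = maf_min, chi2_alpha = chi2_alpha,
                      polarity_min = polarity_min)
  ), class = "filter_cascade_report")
}

#' @export
print.filter_cascade_report <- function(x, ...) {
  cat("filter_cascade_report (cumulative survivors)\n")
  s <- x$survivors
  cat(sprintf("  input: %d | MAF >= %.2g: %d | chi-square < %.2g: %d | polarity >= %.2g: %d\n",
              s[["input"]], x$thresholds$maf_min, s[["maf"]],
              x$thresholds$chi2_alpha, s[["chi_square"]],
              x$thresholds$polarity_min, s[["polarity"]]))
  invisible(x)
}

#' Serialize a cascade report (per-chromosome survivor counts) to JSON
#' @param report a `filter_cascade_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cascade_report <- function(report, path) {
  by_chr <- report$by_chromosome
  jsonlite::write_json(list(
    survivors = as.list(report$survivors),
    thresholds = report$thresholds,
    by_chromosome = if (is.null(by_chr)) NULL else
      data.frame(chromosome = rownames(by_chr), by_chr, check.names = FALSE)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
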