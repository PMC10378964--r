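#' Two-locus linkage disequilibrium from unphased genotypes
#'
#' Estimates haplotype frequencies for a pair of biallelic SNPs from
#' unphased dosage pairs by the EM algorithm: all genotype combinations
#' determine their haplotypes uniquely except the double heterozygote,
#' whose coupling/repulsion split is re-estimated each iteration from the
#' current haplotype frequencies. The log-likelihood is monotone
#' non-decreasing across iterations (asserted). From the converged
#' frequencies: `D = p_AB - p_A p_B`,
#' `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`, and `D' = |D| / D_max`.
#'
#' @param gi,gj dosage vectors (0/1/2, `NA` = missing); pairwise-complete
#'   observations are used.
#' @param tol EM convergence tolerance on the double-heterozygote split
#'   (default 1e-10).
#' @param max_iter maximum EM iterations (default 1000).
#' @return object of class `ld_pair`: list with `r2`, `d_prime`, `D`,
#'   `hap_freq` (named length-4 vector: 00, 01, 10, 11 in B-allele
#'   coding), `n_used`, `em_iterations`.
#' @export
estimate_ld <- function(gi, gj, tol = 1e-10, max_iter = 1000) {
  keep <- !is.na(gi) & !is.na(gj)
  gi <- gi[keep]; gj <- gj[keep]
  n <- length(gi)
  if (!n) stop("undefined LD: no pairwise-complete genotypes")
  if (length(unique(gi)) < 2L || length(unique(gj)) < 2L) {
    stop("undefined LD: monomorphic SNP on the pairwise-complete subset")
  }
  # genotype table counts n[gi, gj]
  tab <- table(factor(gi, levels = 0:2), factor(gj, levels = 0:2))

  # haplotype counts contributed unambiguously; hap index: 1=00,2=01,3=10,4=11
  # (first digit = allele at locus i, second at locus j; allele 1 = allele B)
  base <- numeric(4)
  add <- function(h, k) base[h] <<- base[h] + k
  for (a in 0:2) for (b in 0:2) {
    k <- tab[a + 1, b + 1]
    if (!k) next
    if (a == 1 && b == 1) next # double het handled by EM
    # each individual carries two haplotypes
    ai <- c(if (a >= 1) 1 else 0, if (a == 2) 1 else 0)
    bj <- c(if (b >= 1) 1 else 0, if (b == 2) 1 else 0)
    if (a == 1) ai <- c(1, 0)
    if (b == 1) bj <- c(1, 0)
    if (a != 1 && b != 1) {
      add(1 + 2 * ai[1] + bj[1], 2 * k)
    } else if (a == 1 && b != 1) {
      add(1 + 2 * 1 + bj[1], k); add(1 + 2 * 0 + bj[1], k)
    } else if (a != 1 && b == 1) {
      add(1 + 2 * ai[1] + 1, k); add(1 + 2 * ai[1] + 0, k)
    }
  }
  ndh <- tab[2, 2] # double heterozygotes
  total <- 2 * n

  h <- rep(0.25, 4)
  ll_genotype <- function(h) {
    # genotype log-likelihood under random union of haplotypes
    ll <- 0
    gp <- function(a, b) {
      # P(genotype a,b) as sum over compatible ordered haplotype pairs
      s <- 0
      for (h1 in 1:4) for (h2 in 1:4) {
        a1 <- (h1 - 1) %/% 2; b1 <- (h1 - 1) %% 2
        a2 <- (h2 - 1) %/% 2; b2 <- (h2 - 1) %% 2
        if (a1 + a2 == a && b1 + b2 == b) s <- s + h[h1] * h[h2]
      }
      s
    }
    for (a in 0:2) for (b in 0:2) {
      k <- tab[a + 1, b + 1]
      if (k) ll <- ll + k * log(max(gp(a, b), 1e-300))
    }
    ll
  }

  it <- 0L
  ll_prev <- -Inf
  repeat {
    it <- it + 1L
    # E step: split double hets between coupling (00/11) and repulsion (01/10)
    cpl <- h[1] * h[4]
    rpl <- h[2] * h[3]
    d <- if (cpl + rpl > 0) cpl / (cpl + rpl) else 0.5
    cnt <- base
    cnt[1] <- cnt[1] + ndh * d
    cnt[4] <- cnt[4] + ndh * d
    cnt[2] <- cnt[2] + ndh * (1 - d)
    cnt[3] <- cnt[3] + ndh * (1 - d)
    h_new <- cnt / total
    ll <- ll_genotype(h_new)
    if (ll < ll_prev - 1e-8) {
      stop("EM log-likelihood decreased (internal error)")
    }
    conv <- max(abs(h_new - h)) < tol
    h <- h_new
    ll_prev <- ll
    if (conv || it >= max_iter) break
  }
  names(h) <- c("00", "01", "10", "11")
  pA <- h["10"] + h["11"] # allele B frequency at locus i
  pB <- h["01"] + h["11"] # allele B frequency at locus j
  D <- unname(h["11"] - pA * pB)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) unname(D^2 / denom) else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(D) / dmax else 0
  structure(list(r2 = min(r2, 1), d_prime = min(unname(d_prime), 1), D = D,
                 hap_freq = h, n_used = n, em_iterations = it),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: r2 = %.4f, D' = %.4f (n = %d, %d EM iterations)\n",
              x$r2, x$d_prime, x$n_used, x$em_iterations))
  invisible(x)
}

# Pairwise LD statistic matrix for a small region (NA where undefined).
ld_matrix <- function(g, stat = c("r2", "dprime")) {
  stat <- match.arg(stat)
  m <- ncol(g$dosage)
  L <- matrix(NA_real_, m, m, dimnames = list(g$map$snp_id, g$map$snp_id))
  diag(L) <- 1
  if (m < 2) return(L)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      v <- tryCatch({
        p <- estimate_ld(g$dosage[, i], g$dosage[, j])
        if (stat == "r2") p$r2 else p$d_prime
      }, error = function(e) NA_real_)
      L[i, j] <- v
      L[j, i] <- v
    }
  }
  L
}

# A block [i..j] is valid under the solid-spine rule when the first marker
# is in strong LD with every later member (including j) and the last marker
# with every earlier member (including i).
spine_valid <- function(L, i, j, thr) {
  if (j <= i) return(FALSE)
  ks <- (i + 1):j
  if (any(is.na(L[i, ks])) || any(L[i, ks] < thr)) return(FALSE)
  ks <- i:(j - 1)
  if (any(is.na(L[ks, j])) || any(L[ks, j] < thr)) return(FALSE)
  TRUE
}

# Left-to-right scan over a pairwise LD matrix: each start index is
# extended to the rightmost spine-valid end; emitted blocks do not overlap.
# Returns a list of c(first, last) index pairs.
spine_scan <- function(L, thr) {
  m <- nrow(L)
  blocks <- list()
  i <- 1L
  while (i < m) {
    jbest <- 0L
    for (j in (i + 1L):m) {
      if (spine_valid(L, i, j, thr)) jbest <- j
    }
    if (jbest > 0L) {
      blocks[[length(blocks) + 1L]] <- c(i, jbest)
      i <- jbest + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks
}

# test seam: exercise the scan on an externally supplied LD matrix
spine_scan_for_tests <- function(L, thr) spine_scan(L, thr)

#' Solid-spine haplotype blocks
#'
#' Detects haplotype blocks by the solid-spine-of-LD rule: a run of
#' consecutive markers `[i..j]` forms a block when the first and the last
#' marker are each in strong LD (pairwise statistic at or above
#' `strong_ld_min`) with every other member of the run. Scanning left to
#' right, each start position is extended to the rightmost valid end; the
#' maximal non-overlapping blocks (at least 2 SNPs) are reported in
#' positional order. The spine statistic is `r2` by default (threshold
#' 0.2); classical D'-based spines are available via `stat = "dprime"`
#' (conventional threshold 0.8).
#'
#' @param g a [genotype_matrix()] restricted to one ordered region.
#' @param strong_ld_min spine threshold (default 0.2).
#' @param stat `"r2"` (default) or `"dprime"`.
#' @return data.frame of class `haplo_blocks`: `chromosome`, `first_snp`,
#'   `last_snp`, `first_bp`, `last_bp`, `n_snps`, `snp_ids`
#'   (comma-joined).
#' @export
solid_spine_blocks <- function(g, strong_ld_min = 0.2,
                               stat = c("r2", "dprime")) {
  stat <- match.arg(stat)
  map <- g$map
  if (length(unique(map$chromosome)) > 1) {
    stop("blocks are defined within one chromosome; subset first")
  }
  m <- ncol(g$dosage)
  empty <- data.frame(chromosome = integer(), first_snp = character(),
                      last_snp = character(), first_bp = integer(),
                      last_bp = integer(), n_snps = integer(),
                      snp_ids = character(), stringsAsFactors = FALSE)
  if (m < 2) return(structure(empty, class = c("haplo_blocks", "data.frame")))
  L <- ld_matrix(g, stat = stat)
  blocks <- lapply(spine_scan(L, strong_ld_min), function(ij) {
    i <- ij[1]; j <- ij[2]
    data.frame(
      chromosome = map$chromosome[1],
      first_snp = map$snp_id[i], last_snp = map$snp_id[j],
      first_bp = map$position_bp[i], last_bp = map$position_bp[j],
      n_snps = j - i + 1L,
      snp_ids = paste(map$snp_id[i:j], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(blocks)) do.call(rbind, blocks) else empty
  structure(out, class = c("haplo_blocks", "data.frame"))
}

#' Map SNPs to genes within a window
#'
#' A SNP maps to a gene when both lie on the same chromosome and the
#' window `[position - window_bp, position + window_bp]` overlaps the gene
#' body `[start_bp, end_bp]` (1-based inclusive coordinates, non-empty
#' intersection). The signed distance is 0 when the SNP lies inside the
#' gene, positive when the gene starts downstream (gene to the right of
#' the SNP), negative when the gene ends upstream (gene to the left).
#'
#' @param snps data.frame with `snp_id`, `chromosome`, `position_bp` (a
#'   [marker_map()] or scan rows).
#' @param genes data.frame from [read_genes()] (`gene_id`, `chromosome`,
#'   `start_bp`, `end_bp`).
#' @param window_bp window half-width in bp (default 2 Mb).
#' @return data.frame with `snp_id`, `gene_id`, `chromosome`,
#'   `position_bp`, `start_bp`, `end_bp`, `distance_bp` (signed),
#'   `relation` ("within" / "left" = gene left of SNP / "right").
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 2e6) {
  need <- c("snp_id", "chromosome", "position_bp")
  stopifnot(all(need %in% names(snps)),
            all(c("gene_id", "chromosome", "start_bp", "end_bp") %in%
                  names(genes)))
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    chr <- snps$chromosome[i]
    pos <- snps$position_bp[i]
    cand <- genes[genes$chromosome == chr &
                    genes$start_bp <= pos + window_bp &
                    genes$end_bp >= pos - window_bp, , drop = FALSE]
    if (!nrow(cand)) next
    dist <- ifelse(pos < cand$start_bp, cand$start_bp - pos,
                   ifelse(pos > cand$end_bp, cand$end_bp - pos, 0L))
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snps$snp_id[i], gene_id = cand$gene_id,
      chromosome = chr, position_bp = pos,
      start_bp = cand$start_bp, end_bp = cand$end_bp,
      distance_bp = as.integer(dist),
      relation = ifelse(dist == 0L, "within",
                        ifelse(dist < 0L, "left", "right")),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), gene_id = character(),
               chromosome = integer(), position_bp = integer(),
               start_bp = integer(), end_bp = integer(),
               distance_bp = integer(), relation = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Syntenic LD screen between significant SNPs and gene-region SNPs
#'
#' Estimates r2 for every (significant SNP, gene SNP) pair lying on the
#' same chromosome — regardless of their bp separation — and keeps pairs
#' with `r2 >= r2_min`. Explicitly requested cross-chromosome pairs are an
#' error (LD here is syntenic by definition).
#'
#' @param sig_snps,gene_snps character vectors of SNP ids present in `g`.
#' @param g a [genotype_matrix()] containing both sets.
#' @param r2_min retention threshold (default 0.2).
#' @param pairs optional explicit data.frame (`snp_i`, `snp_j`) overriding
#'   the all-pairs construction.
#' @return data.frame with `snp_i`, `snp_j`, `chromosome`, `r2`,
#'   `d_prime`, `n_used`.
#' @export
syntenic_ld_screen <- function(sig_snps, gene_snps, g, r2_min = 0.2,
                               pairs = NULL) {
  map <- g$map
  chr_of <- setNames(map$chromosome, map$snp_id)
  if (is.null(pairs)) {
    pairs <- expand.grid(snp_i = unique(sig_snps), snp_j = unique(gene_snps),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$snp_i != pairs$snp_j, , drop = FALSE]
    pairs <- pairs[chr_of[pairs$snp_i] == chr_of[pairs$snp_j], ,
                   drop = FALSE]
  } else {
    bad <- chr_of[pairs$snp_i] != chr_of[pairs$snp_j]
    if (any(bad)) {
      stop("cross-chromosome pair(s) requested (syntenic LD only): ",
           paste(pairs$snp_i[bad], pairs$snp_j[bad], sep = "-",
                 collapse = ", "))
    }
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    si <- pairs$snp_i[i]; sj <- pairs$snp_j[i]
    lp <- tryCatch(estimate_ld(g$dosage[, si], g$dosage[, sj]),
                   error = function(e) NULL)
    if (is.null(lp) || is.na(lp$r2) || lp$r2 < r2_min) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_i = si, snp_j = sj, chromosome = unname(chr_of[si]),
      r2 = lp$r2, d_prime = lp$d_prime, n_used = lp$n_used,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_i = character(), snp_j = character(),
               chromosome = integer(), r2 = numeric(), d_prime = numeric(),
               n_used = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
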