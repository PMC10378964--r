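#' Generalized quasi-likelihood score (GQLS) test for one SNP
#'
#' Score test of marker-trait association in which the allelic proportion
#' `y` (0, 1/2, 1 for dosages 0/1/2) is the response, the 0/1 disease
#' status `x` the covariate, and genetic relatedness enters through the
#' working covariance. Under the null logistic mean model the SNP allele
#' frequency does not depend on status; the fixed convention implemented
#' here is:
#' \itemize{
#'   \item working covariance `V = v(mu0) * K` with variance function
#'     `v(mu) = mu(1-mu)/2` (binomial with 2 alleles, on the proportion
#'     scale) and `K` the kinship correlation matrix;
#'   \item null mean `mu0 = (1' K^{-1} y) / (1' K^{-1} 1)` (GLS estimate);
#'   \item score `U = x' V^{-1} (y - mu0)` with null variance
#'     `Var(U) = x' V^{-1} x - (x' V^{-1} 1)^2 / (1' V^{-1} 1)`;
#'   \item statistic `T = U^2 / Var(U)`, referred to chi-square with 1 df.
#' }
#' `T` is invariant to the scale of `v`, to allele relabeling
#' (`y -> 1 - y`), and with `K = I` it reduces to the classic score test of
#' a logistic-type mean model.
#'
#' @param y allelic proportions in `{0, 1/2, 1}`; `NA` allowed (dropped
#'   pairwise together with the corresponding `x`/`K` entries).
#' @param x 0/1 disease status.
#' @param K kinship correlation matrix (unit-scale diagonal, symmetric
#'   PSD); `NULL` means independence (identity).
#' @param Kinv optional pre-computed `solve(K)` (used by [run_gwas()]; only
#'   valid when `y` has no missing entries).
#' @return list with `T`, `p_value`, `sign` (direction of `U`), `mu0`,
#'   `n_used`, `monomorphic`.
#' @export
gqls_test <- function(y, x, K = NULL, Kinv = NULL) {
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]; x <- x[keep]
    if (!is.null(K)) K <- K[keep, keep, drop = FALSE]
    Kinv <- NULL
  }
  n <- length(y)
  if (length(unique(x)) < 2L) {
    stop("cohort error: only one phenotype class present")
  }
  if (length(unique(y)) < 2L) {
    return(list(T = NA_real_, p_value = 1, sign = 0L, mu0 = mean(y),
                n_used = n, monomorphic = TRUE))
  }
  if (is.null(Kinv)) {
    if (is.null(K)) {
      k1 <- rep(1, n); ky <- y; kx <- x
    } else {
      sol <- solve(K, cbind(1, y, x))
      k1 <- sol[, 1]; ky <- sol[, 2]; kx <- sol[, 3]
    }
  } else {
    k1 <- Kinv$k1; ky <- Kinv$Kinv %*% y; kx <- Kinv$kx
  }
  s11 <- sum(k1)
  mu0 <- sum(ky) / s11
  mu0 <- min(max(mu0, 1e-10), 1 - 1e-10)
  v <- mu0 * (1 - mu0) / 2
  U <- sum(x * ky) - mu0 * sum(x * k1)
  quad <- sum(x * kx) - sum(x * k1)^2 / s11
  T_stat <- U^2 / (v * quad)
  list(T = as.numeric(T_stat),
       p_value = pchisq(as.numeric(T_stat), df = 1, lower.tail = FALSE),
       sign = as.integer(sign(U)),
       mu0 = mu0, n_used = n, monomorphic = FALSE)
}

#' Genome-wide GQLS association scan
#'
#' Runs [gqls_test()] one SNP at a time over a QC'd genotype matrix. The
#' kinship matrix is factorized once and reused for every SNP without
#' missing calls; SNPs with missing genotypes fall back to a
#' pairwise-complete solve. MAF is recorded from non-missing calls.
#'
#' @param g a [genotype_matrix()].
#' @param status named 0/1 status vector covering the genotyped animals.
#' @param K kinship matrix with dimnames covering `animal_ids(g)`; `NULL`
#'   for independence.
#' @param estimate_dispersion divide all statistics by a moment estimate of
#'   overdispersion (the mean of `T` across polymorphic SNPs); default
#'   `FALSE`.
#' @return a `data.frame` of class `gqls_scan`: one row per SNP with
#'   `snp_id`, `chromosome`, `position_bp`, `sign`, `T`, `p_value`, `maf`,
#'   `n_used`, `monomorphic`.
#' @export
run_gwas <- function(g, status, K = NULL, estimate_dispersion = FALSE) {
  ids <- animal_ids(g)
  miss_ph <- setdiff(ids, names(status))
  if (length(miss_ph)) {
    stop("alignment error: genotyped animals without phenotype: ",
         paste(utils::head(miss_ph, 5), collapse = ", "))
  }
  x <- as.numeric(status[ids])
  if (!is.null(K)) {
    if (is.null(dimnames(K))) {
      if (nrow(K) != length(ids)) stop("alignment error: unnamed K size")
      dimnames(K) <- list(ids, ids)
    }
    miss_k <- setdiff(ids, rownames(K))
    if (length(miss_k)) {
      stop("alignment error: genotyped animals absent from K: ",
           paste(utils::head(miss_k, 5), collapse = ", "))
    }
    K <- K[ids, ids]
  }
  m <- ncol(g$dosage)
  if (m == 0L) {
    warning("no SNPs to test")
    out <- data.frame(snp_id = character(), chromosome = integer(),
                      position_bp = integer(), sign = integer(),
                      T = numeric(), p_value = numeric(), maf = numeric(),
                      n_used = integer(), monomorphic = logical())
    class(out) <- c("gqls_scan", "data.frame")
    return(out)
  }
  pre <- NULL
  if (!is.null(K)) {
    Ki <- solve(K)
    pre <- list(Kinv = Ki, k1 = as.numeric(Ki %*% rep(1, length(ids))),
                kx = as.numeric(Ki %*% x))
  } else {
    pre <- list(Kinv = NULL, k1 = rep(1, length(ids)), kx = x)
  }

  Tv <- numeric(m); pv <- numeric(m); sg <- integer(m)
  nu <- integer(m); mono <- logical(m); maf <- numeric(m)
  for (j in seq_len(m)) {
    dj <- g$dosage[, j]
    pj <- mean(dj, na.rm = TRUE) / 2
    maf[j] <- min(pj, 1 - pj)
    yj <- dj / 2
    res <- if (anyNA(yj) || is.null(K)) {
      if (anyNA(yj)) gqls_test(yj, x, K = K)
      else gqls_test(yj, x, K = NULL)
    } else {
      if (length(unique(yj)) < 2L) {
        list(T = NA_real_, p_value = 1, sign = 0L, n_used = length(yj),
             monomorphic = TRUE)
      } else {
        gqls_test(yj, x, K = K, Kinv = pre)
      }
    }
    Tv[j] <- res$T; pv[j] <- res$p_value; sg[j] <- res$sign
    nu[j] <- res$n_used; mono[j] <- res$monomorphic
  }
  if (estimate_dispersion) {
    lambda <- mean(Tv[!mono], na.rm = TRUE)
    if (is.finite(lambda) && lambda > 0) {
      Tv <- Tv / lambda
      pv <- ifelse(mono, 1, pchisq(Tv, 1, lower.tail = FALSE))
    }
  }
  out <- data.frame(
    snp_id = g$map$snp_id,
    chromosome = g$map$chromosome,
    position_bp = g$map$position_bp,
    sign = sg, T = Tv, p_value = pv, maf = maf,
    n_used = nu, monomorphic = mono,
    stringsAsFactors = FALSE
  )
  if (estimate_dispersion) attr(out, "dispersion") <- lambda
  class(out) <- c("gqls_scan", "data.frame")
  out
}

#' @export
print.gqls_scan <- function(x, ...) {
  cat("gqls_scan:", nrow(x), "SNPs on", length(unique(x$chromosome)),
      "chromosome(s);", sum(x$monomorphic), "monomorphic\n")
  if ("q_value" %in% names(x)) {
    for (cut in c(0.01, 0.05, 0.10)) {
      cat(sprintf("  pFDR <= %g%%: %d SNPs\n", 100 * cut,
                  sum(x$q_value <= cut, na.rm = TRUE)))
    }
  } else if (nrow(x)) {
    cat("  min p =", format(min(x$p_value), digits = 3),
        "(run chromosome_pfdr() for q-values)\n")
  }
  invisible(x)
}

# Storey q-values for one vector of p-values.
# pi0 by the smoother method over lambda = 0.05..0.95 unless m < 100
# (fallback pi0 = 1, where q-values coincide with Benjamini-Hochberg).
storey_qvalues <- function(p, small_m = 100L) {
  m <- length(p)
  if (!m) return(list(q = numeric(0), pi0 = NA_real_, method = "none"))
  if (m < small_m) {
    pi0 <- 1
    method <- "fallback_pi0_1"
  } else {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) min(pi0_l)
           else predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
    method <- "smoother"
  }
  o <- order(p)
  q_o <- pi0 * m * p[o] / seq_len(m)
  q_o <- rev(cummin(rev(q_o)))
  q_o <- pmin(q_o, 1)
  q <- numeric(m)
  q[o] <- q_o
  list(q = q, pi0 = pi0, method = method)
}

#' Chromosome-wise positive-FDR q-values and significance tiers
#'
#' Computes Storey-style q-values independently within each chromosome
#' (pi0 by the smoother method over lambda in 0.05..0.95; chromosomes with
#' fewer than 100 SNPs fall back to pi0 = 1, where the q-values equal
#' Benjamini-Hochberg adjusted p-values) and assigns each SNP the smallest
#' pFDR tier in `tiers` whose cutoff its q-value meets.
#'
#' @param scan a `gqls_scan` (or any data.frame with `p_value` and
#'   `chromosome`).
#' @param tiers pFDR cutoffs (default 1%, 5%, 10%).
#' @return the scan with columns `q_value` and `pfdr_tier` (`"1%"`, `"5%"`,
#'   `"10%"` or `"ns"`) added; per-chromosome pi0 estimates are attached as
#'   attribute `pi0`.
#' @export
chromosome_pfdr <- function(scan, tiers = c(0.01, 0.05, 0.10)) {
  stopifnot(all(c("p_value", "chromosome") %in% names(scan)))
  tiers <- sort(tiers)
  q <- rep(NA_real_, nrow(scan))
  pi0s <- list()
  for (chr in unique(scan$chromosome)) {
    sel <- scan$chromosome == chr
    res <- storey_qvalues(scan$p_value[sel])
    q[sel] <- res$q
    pi0s[[as.character(chr)]] <- list(pi0 = res$pi0, method = res$method)
  }
  tier_lab <- sprintf("%g%%", 100 * tiers)
  tier <- rep("ns", nrow(scan))
  for (i in rev(seq_along(tiers))) tier[q <= tiers[i]] <- tier_lab[i]
  scan$q_value <- q
  scan$pfdr_tier <- tier
  attr(scan, "pi0") <- pi0s
  if (!inherits(scan, "gqls_scan")) {
    class(scan) <- c("gqls_scan", class(scan))
  }
  scan
}

#' Manhattan-plot export of a q-annotated scan
#'
#' Emits one row per SNP with `-log10(q)` truncated at `cap` and a flag for
#' values that exceeded the cap.
#'
#' @param scan a scan with `q_value`.
#' @param path optional TSV output path.
#' @param cap truncation for `-log10(q)` (default 6).
#' @return data.frame with `chromosome`, `position_bp`, `snp_id`,
#'   `neg_log10_q`, `exceeds_cap`.
#' @export
manhattan_table <- function(scan, path = NULL, cap = 6) {
  stopifnot("q_value" %in% names(scan))
  nl <- -log10(pmax(scan$q_value, 1e-300))
  out <- data.frame(
    chromosome = scan$chromosome,
    position_bp = scan$position_bp,
    snp_id = scan$snp_id,
    neg_log10_q = pmin(nl, cap),
    exceeds_cap = nl > cap,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
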