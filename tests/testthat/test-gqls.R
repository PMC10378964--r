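test_that("worked example: perfectly separated alleles give T = 12", {
  r <- gqls_test(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$mu0, 0.5)
  expect_equal(r$T, 12, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(12, 1, lower.tail = FALSE))
})

test_that("monomorphic SNPs are flagged with p = 1", {
  r <- gqls_test(rep(0.5, 8), rep(c(0, 1), 4))
  expect_true(r$monomorphic)
  expect_equal(r$p_value, 1)
  expect_error(gqls_test(c(0, 0.5, 1), c(1, 1, 1)), "one phenotype class")
})

test_that("statistic is invariant to which allele is counted", {
  set.seed(61)
  for (i in 1:10) {
    n <- 40
    y <- rbinom(n, 2, 0.4) / 2
    x <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    expect_equal(gqls_test(y, x)$T, gqls_test(1 - y, x)$T,
                 tolerance = 1e-10)
  }
})

test_that("T matches a dense GLS score oracle with identity and random PSD K", {
  set.seed(67)
  checked <- 0
  while (checked < 50) {
    n <- sample(10:30, 1)
    y <- rbinom(n, 2, runif(1, 0.2, 0.8)) / 2
    x <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    Z <- matrix(rnorm(n * n), n)
    K <- 0.5 * diag(n) + 0.5 * crossprod(Z) / n
    K <- K / mean(diag(K))
    for (Kuse in list(NULL, K)) {
      Ki <- if (is.null(Kuse)) diag(n) else solve(Kuse)
      mu0 <- sum(Ki %*% y) / sum(Ki)
      v <- mu0 * (1 - mu0) / 2
      U <- as.numeric(t(x) %*% Ki %*% (y - mu0)) / v
      VarU <- (as.numeric(t(x) %*% Ki %*% x) -
                 as.numeric(t(x) %*% Ki %*% rep(1, n))^2 / sum(Ki)) / v
      r <- gqls_test(y, x, K = Kuse)
      expect_equal(r$T, U^2 / VarU, tolerance = 1e-10)
    }
    checked <- checked + 1
  }
})

test_that("missing allelic proportions are dropped pairwise", {
  y <- c(0, 0.5, 1, NA, 1, 0)
  x <- c(0, 0, 1, 1, 1, 0)
  r <- gqls_test(y, x)
  expect_equal(r$n_used, 5L)
  expect_equal(r$T, gqls_test(y[-4], x[-4])$T)
})

test_that("scan aligns ids, records MAF, and flags empty input", {
  pc <- planted_cohort(71, n = 60, m = 30)
  scan <- run_gwas(pc$g, pc$status)
  expect_equal(nrow(scan), 30L)
  expect_equal(scan$maf[1],
               compute_maf(pc$g$dosage[, 1]))
  # planted informative SNP is overwhelmingly significant
  expect_lt(scan$p_value[pc$planted], 1e-6)
  expect_error(run_gwas(pc$g, pc$status[-1]), "alignment")
  empty <- subset_genotypes(pc$g, snps = integer(0))
  expect_warning(s0 <- run_gwas(empty, pc$status), "no SNPs")
  expect_equal(nrow(s0), 0L)
})

test_that("null p-values are uniform under permuted statuses", {
  set.seed(73)
  g <- random_genotypes(73, n = 150, m = 400)
  status <- setNames(rbinom(150, 1, 0.5), animal_ids(g))
  scan <- run_gwas(g, status)
  ks <- suppressWarnings(stats::ks.test(scan$p_value[!scan$monomorphic],
                                        "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kinship-aware scan reuses the factorization correctly", {
  set.seed(79)
  pc <- planted_cohort(79, n = 50, m = 12)
  Z <- matrix(rnorm(50 * 50), 50)
  K <- 0.5 * diag(50) + 0.5 * crossprod(Z) / 50
  dimnames(K) <- list(animal_ids(pc$g), animal_ids(pc$g))
  scan <- run_gwas(pc$g, pc$status, K = K)
  for (j in c(1, 5, 12)) {
    direct <- gqls_test(pc$g$dosage[, j] / 2, as.numeric(pc$status), K = K)
    expect_equal(scan$T[j], direct$T, tolerance = 1e-10)
  }
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  p <- c(0.001, 0.02, 0.03, 0.8)
  scan <- data.frame(snp_id = paste0("s", 1:4), chromosome = 1,
                     position_bp = 1:4, p_value = p)
  out <- chromosome_pfdr(scan)
  expect_equal(out$q_value, c(0.004, 0.04, 0.04, 0.8), tolerance = 1e-12)
  expect_equal(out$q_value, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(attr(out, "pi0")[["1"]]$method, "fallback_pi0_1")
  expect_equal(out$pfdr_tier, c("1%", "5%", "5%", "ns"))
})

test_that("all-ones p-vector gives q = 1 and tier ns", {
  scan <- data.frame(snp_id = paste0("s", 1:6), chromosome = 2,
                     position_bp = 1:6, p_value = rep(1, 6))
  out <- chromosome_pfdr(scan)
  expect_true(all(out$q_value == 1))
  expect_true(all(out$pfdr_tier == "ns"))
})

test_that("q-values are monotone in p within each chromosome", {
  set.seed(83)
  for (rep in 1:5) {
    m <- sample(c(20, 150, 400), 1)
    scan <- data.frame(snp_id = seq_len(m),
                       chromosome = sample(1:3, m, replace = TRUE),
                       position_bp = seq_len(m),
                       p_value = runif(m)^sample(1:3, 1))
    out <- chromosome_pfdr(scan)
    for (chr in unique(out$chromosome)) {
      sub <- out[out$chromosome == chr, ]
      sub <- sub[order(sub$p_value), ]
      expect_true(all(diff(sub$q_value) >= -1e-12))
      expect_true(all(sub$q_value <= 1 + 1e-12))
    }
  }
})

test_that("manhattan export truncates -log10(q) at the cap", {
  scan <- data.frame(snp_id = c("a", "b"), chromosome = c(1, 1),
                     position_bp = c(1, 2), p_value = c(1e-10, 0.5),
                     q_value = c(1e-9, 0.5))
  mt <- manhattan_table(scan)
  expect_equal(mt$neg_log10_q, c(6, -log10(0.5)))
  expect_identical(mt$exceeds_cap, c(TRUE, FALSE))
})
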