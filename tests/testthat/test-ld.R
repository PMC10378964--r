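test_that("complete LD and exact independence are recovered", {
  gi <- c(0, 0, 1, 1, 2, 2)
  r <- estimate_ld(gi, gi)
  expect_equal(r$r2, 1, tolerance = 1e-9)
  expect_equal(r$d_prime, 1, tolerance = 1e-9)

  # genotype counts exactly matching independence products: r2 = 0
  gi2 <- rep(c(0, 1, 2), times = c(4, 4, 4)) # p = 0.5 per locus
  gj2 <- rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2), times = c(1, 2, 1, 2, 4, 2, 1, 2, 1))
  # build a 12-individual table whose joint counts factorize
  gi3 <- rep(c(0, 0, 0, 1, 1, 1, 2, 2, 2), times = c(1, 2, 1, 2, 4, 2, 1, 2, 1))
  gj3 <- rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2), times = c(1, 2, 1, 2, 4, 2, 1, 2, 1))
  r0 <- estimate_ld(gi3, gj3)
  expect_equal(r0$r2, 0, tolerance = 1e-9)
})

test_that("EM r2 tracks direct haplotype counting on phased truth", {
  # linked-marker regime: strong |D'| pairs, phase reconstructed from the
  # collapsed unphased genotypes and compared with counting the simulated
  # haplotypes themselves
  set.seed(212)
  pairs_checked <- 0
  for (k in 1:200) {
    s <- phased_pair_fixture(n = 5000)
    est <- tryCatch(estimate_ld(s$gi, s$gj), error = function(e) NULL)
    if (is.null(est)) next
    pA <- mean(s$a); pB <- mean(s$b)
    denom <- pA * (1 - pA) * pB * (1 - pB)
    if (denom < 1e-12) next
    r2_true <- (mean(s$a & s$b) - pA * pB)^2 / denom
    expect_lt(abs(est$r2 - r2_true), 0.02)
    pairs_checked <- pairs_checked + 1
  }
  expect_gte(pairs_checked, 150)
})

test_that("r2 is invariant to allele-label swaps at either locus", {
  set.seed(221)
  for (k in 1:10) {
    gi <- rbinom(60, 2, runif(1, 0.25, 0.75))
    gj <- rbinom(60, 2, runif(1, 0.25, 0.75))
    base <- tryCatch(estimate_ld(gi, gj), error = function(e) NULL)
    if (is.null(base)) next
    expect_equal(estimate_ld(2 - gi, gj)$r2, base$r2, tolerance = 1e-9)
    expect_equal(estimate_ld(gi, 2 - gj)$r2, base$r2, tolerance = 1e-9)
  }
})

test_that("monomorphic input is an undefined-LD error", {
  expect_error(estimate_ld(rep(1, 10), rbinom(10, 2, 0.5)), "monomorphic")
})

test_that("solid-spine blocks: canonical 3-SNP cases", {
  # all pairwise r2 = 1: one block of 3
  d <- c(0, 0, 1, 1, 2, 2)
  g3 <- genotype_matrix(matrix(c(d, d, d), ncol = 3,
                               dimnames = list(sprintf("a%d", 1:6), NULL)),
                        marker_map(c("s1", "s2", "s3"), c(1, 1, 1),
                                   c(100, 200, 300)))
  b <- solid_spine_blocks(g3, strong_ld_min = 0.2)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_snps, 3L)

  # independent SNPs: no blocks
  set.seed(227)
  dd <- sapply(1:3, function(i) rbinom(200, 2, 0.5))
  rownames(dd) <- sprintf("b%03d", 1:200)
  g0 <- genotype_matrix(dd, g3$map)
  b0 <- solid_spine_blocks(g0, strong_ld_min = 0.2)
  expect_equal(nrow(b0), 0L)
})

test_that("greedy spine equals the exhaustive oracle on random fixtures", {
  set.seed(229)
  for (k in 1:12) {
    m <- sample(4:8, 1)
    # random symmetric LD-like matrix
    L <- matrix(runif(m * m), m)
    L[lower.tri(L)] <- t(L)[lower.tri(L)]
    diag(L) <- 1
    oracle <- oracle_spine_blocks(L, 0.5)
    # drive the implementation through its ld_matrix seam: rebuild a
    # genotype set is unnecessary — validate spine_valid + scan logic by
    # reusing the internal helpers
    impl <- spastigen:::spine_scan_for_tests(L, 0.5)
    expect_identical(impl, oracle)
  }
})

test_that("worked spine: 0.9 / 0.9 adjacent but weak ends stop at two", {
  L <- matrix(c(1, 0.9, 0.05,
                0.9, 1, 0.9,
                0.05, 0.9, 1), 3, byrow = TRUE)
  impl <- spastigen:::spine_scan_for_tests(L, 0.2)
  expect_identical(impl, list(c(1L, 2L)))
})

test_that("SNP-to-gene mapping honours the 2 Mb window and containment", {
  genes <- data.frame(gene_id = "CACNA1A_like", chromosome = 7,
                      start_bp = 13249309L, end_bp = 13506224L)
  snps <- data.frame(snp_id = c("inside", "far_left_ok", "too_far"),
                     chromosome = 7,
                     position_bp = c(13282230L,
                                     13249309L - 2000000L,
                                     13506224L + 2000001L))
  out <- map_snps_to_genes(snps, genes, window_bp = 2e6)
  expect_setequal(out$snp_id, c("inside", "far_left_ok"))
  inside <- out[out$snp_id == "inside", ]
  expect_equal(inside$distance_bp, 0L)
  expect_equal(inside$relation, "within")
  edge <- out[out$snp_id == "far_left_ok", ]
  expect_equal(edge$distance_bp, 2000000L)
  expect_equal(edge$relation, "right")
})

test_that("cross-chromosome SNPs never map; malformed rows are skipped", {
  genes <- data.frame(gene_id = "g1", chromosome = 2,
                      start_bp = 100L, end_bp = 200L)
  snps <- data.frame(snp_id = "s", chromosome = 3, position_bp = 150L)
  expect_equal(nrow(map_snps_to_genes(snps, genes)), 0L)

  td <- withr::local_tempdir()
  writeLines(c("1\t100\t500\tgood", "1\tnotanumber\t200\tbad"),
             file.path(td, "g.bed"))
  expect_warning(gg <- read_genes(file.path(td, "g.bed")), "malformed")
  expect_equal(nrow(gg), 1L)
  expect_equal(gg$start_bp, 101L) # BED 0-based start converted
})

test_that("syntenic screen keeps high-r2 same-chromosome pairs only", {
  d <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  noise <- rbinom(10, 2, 0.5)
  dose <- cbind(d, d, noise)
  rownames(dose) <- sprintf("a%02d", 1:10)
  g <- genotype_matrix(dose, marker_map(c("sigA", "geneA", "geneB"),
                                        c(1, 1, 1), c(100, 200, 300)))
  out <- syntenic_ld_screen("sigA", c("geneA", "geneB"), g, r2_min = 0.2)
  expect_true("geneA" %in% out$snp_j)
  out_all <- syntenic_ld_screen("sigA", c("geneA", "geneB"), g, r2_min = 0)
  expect_equal(nrow(out_all), 2L)

  g2 <- genotype_matrix(dose, marker_map(c("sigA", "geneA", "geneB"),
                                         c(1, 2, 2), c(100, 200, 300)))
  expect_error(
    syntenic_ld_screen("sigA", "geneA", g2,
                       pairs = data.frame(snp_i = "sigA", snp_j = "geneA")),
    "cross-chromosome")
  # auto-paired sets on different chromosomes simply produce no pairs
  expect_equal(nrow(syntenic_ld_screen("sigA", "geneA", g2)), 0L)
})
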