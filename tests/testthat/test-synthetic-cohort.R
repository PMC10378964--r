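test_that("smallest pedigree is a founder trio and topological order holds", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    offspring_per_mating = 1, n_phenotyped = 2,
                    n_training = 1, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3L)
  child <- ped[ped$generation == 1L, ]
  founders <- ped$animal[ped$generation == 0L]
  expect_setequal(c(child$sire, child$dam), founders)

  cfg2 <- sim_config(n_founders = 10, n_generations = 3, seed = 5)
  ped2 <- simulate_pedigree(cfg2)
  pos <- setNames(seq_len(nrow(ped2)), ped2$animal)
  for (i in seq_len(nrow(ped2))) {
    for (p in c(ped2$sire[i], ped2$dam[i])) {
      if (p != "0") expect_lt(pos[[p]], i)
    }
  }
})

test_that("same seed reproduces pedigree, genotypes and phenotypes bitwise", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 15,
                    n_founders = 20, n_phenotyped = 30, n_training = 10,
                    seed = 11)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$pedigree, b2$pedigree)
  expect_identical(b1$genotypes$dosage, b2$genotypes$dosage)
  expect_identical(b1$phenotypes, b2$phenotypes)
  expect_identical(b1$true_qtl, b2$true_qtl)
})

test_that("invalid configuration values name the offending field", {
  expect_error(sim_config(prevalence_target = 1.2), "prevalence_target")
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(founder_maf_range = c(0, 0.6)),
               "founder_maf_range")
})

test_that("founder allele frequencies follow the requested MAF", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 500,
                    n_founders = 40, n_generations = 1,
                    founder_maf_range = c(0.5, 0.5), missing_rate = 0,
                    n_phenotyped = 10, n_training = 2, seed = 21)
  ped <- simulate_pedigree(cfg)
  map <- simulate_marker_map(cfg)
  g <- simulate_genotypes(ped, map, cfg)
  founders <- ped$animal[ped$generation == 0L]
  md <- mean(g$dosage[founders, ])
  se <- sqrt(2 * 0.5 * 0.5 / (length(founders) * nrow(map)))
  expect_lt(abs(md - 1.0), 3 * se)
})

test_that("no missing calls are injected when missing_rate is zero", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 30,
                    n_founders = 10, missing_rate = 0, n_phenotyped = 10,
                    n_training = 2, seed = 2)
  g <- simulate_genotypes(simulate_pedigree(cfg), simulate_marker_map(cfg),
                          cfg)
  expect_false(anyNA(g$dosage))
})

test_that("gene dropping is Mendelian-consistent (brute-force trio check)", {
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 25,
                    n_founders = 16, missing_rate = 0, n_phenotyped = 20,
                    n_training = 5, seed = 13)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, simulate_marker_map(cfg), cfg)
  hap <- attr(g, "haplotypes")
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  violations <- 0L
  for (i in which(ped$sire != "0")) {
    s <- idx[[ped$sire[i]]]
    d <- idx[[ped$dam[i]]]
    # paternal haplotype must match one of the sire's alleles SNP-wise,
    # maternal likewise
    violations <- violations +
      sum(hap$h1[i, ] != hap$h1[s, ] & hap$h1[i, ] != hap$h2[s, ]) +
      sum(hap$h2[i, ] != hap$h1[d, ] & hap$h2[i, ] != hap$h2[d, ])
  }
  expect_identical(violations, 0L)
})

test_that("one known parent is rejected by the gene dropper", {
  cfg <- sim_config(seed = 1)
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "0"))
  map <- marker_map("s1", 1, 100)
  expect_error(simulate_genotypes(ped, map, cfg), "exactly one known parent")
})

test_that("quantile thresholding hits the target case count", {
  # cohort-scale prevalence: 157 affected of 265
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 10,
                    prevalence_target = 0.5925, seed = 7)
  b <- simulate_cohort(cfg)
  expect_equal(sum(b$phenotypes == 1L), 157L)
  expect_equal(length(b$phenotypes), 265L)
  expect_equal(round(100 * b$realized_prevalence, 2), 59.25)

  # exactly half affected for even n at prevalence 0.5
  cfg2 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 30,
                     n_qtl = 2, prevalence_target = 0.5,
                     n_phenotyped = 100, n_training = 20, seed = 9)
  b2 <- simulate_cohort(cfg2)
  expect_equal(sum(b2$phenotypes == 1L), 50L)
})

test_that("training and testing sets partition the phenotyped cohort", {
  b <- simulate_cohort(sim_config(n_chromosomes = 1,
                                  snps_per_chromosome = 10, seed = 4))
  expect_length(intersect(b$training_ids, b$testing_ids), 0)
  expect_setequal(c(b$training_ids, b$testing_ids), names(b$phenotypes))
  expect_true(all(names(b$phenotypes) %in% b$pedigree$animal))
})

test_that("zero heritability decouples status from genotype", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 60,
                    h2_underlying = 0, n_qtl = 0, missing_rate = 0,
                    n_phenotyped = 120, n_training = 20, seed = 17)
  b <- simulate_cohort(cfg)
  scan <- run_gwas(b$genotypes, b$phenotypes)
  # nominal type-I behaviour: about 5% of SNPs below p = 0.05
  expect_lt(mean(scan$p_value < 0.05), 0.15)
})

test_that("QTL variance exceeding the genetic-variance target errors", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 30,
                    h2_underlying = 0.05, n_qtl = 10, qtl_effect_sd = 2,
                    n_phenotyped = 50, n_training = 10, seed = 19)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, simulate_marker_map(cfg), cfg)
  expect_error(simulate_liability_phenotypes(ped, g, cfg),
               "exceeds the target genetic variance")
})

test_that("written cohort files round-trip through the readers", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 8,
                    n_founders = 12, n_phenotyped = 20, n_training = 5,
                    missing_rate = 0.05, seed = 23)
  b <- simulate_cohort(cfg)
  prefix <- file.path(withr::local_tempdir(), "coh")
  write_cohort(b, prefix)
  g2 <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  # dosages agree up to allele-label polarization per SNP
  d1 <- b$genotypes$dosage
  d2 <- g2$dosage[rownames(d1), ]
  for (j in seq_len(ncol(d1))) {
    same <- isTRUE(all.equal(d1[, j], d2[, j]))
    flipped <- isTRUE(all.equal(d1[, j], 2L - d2[, j]))
    expect_true(same || flipped)
  }
  ph <- suppressWarnings(read_phenotypes(paste0(prefix, "_phenotypes.csv")))
  expect_identical(ph[names(b$phenotypes)], b$phenotypes)
  genes <- read_genes(paste0(prefix, "_genes.bed"))
  expect_equal(nrow(genes), nrow(b$true_qtl))
})
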