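test_that("the same seed reproduces the VIM vector bitwise", {
  pc <- planted_cohort(111, n = 80, m = 60)
  r1 <- run_forest(pc$g, pc$status, n_trees = 25, seed = 5)
  r2 <- run_forest(pc$g, pc$status, n_trees = 25, seed = 5)
  expect_identical(r1$vim_pct, r2$vim_pct)
  expect_identical(r1$oob_per_class, r2$oob_per_class)
  r3 <- run_forest(pc$g, pc$status, n_trees = 25, seed = 6)
  expect_false(identical(r1$vim_pct, r3$vim_pct))
})

test_that("pure-noise SNPs earn importances near zero", {
  set.seed(113)
  g <- random_genotypes(113, n = 150, m = 400)
  status <- setNames(rbinom(150, 1, 0.5), animal_ids(g))
  r <- run_forest(g, status, n_trees = 50, seed = 1)
  expect_lt(median(abs(r$vim_pct)), 1)
  expect_lt(mean(r$vim_pct > 0), 0.6)
})

test_that("a perfectly informative SNP dominates the importance ranking", {
  hits <- 0L
  for (s in 1:10) {
    pc <- planted_cohort(120 + s, n = 150, m = 500)
    r <- run_forest(pc$g, pc$status, n_trees = 75, seed = s)
    if (which.max(r$vim_pct) == pc$planted) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("single-class training sets are rejected", {
  pc <- planted_cohort(131, n = 40, m = 20)
  all1 <- setNames(rep(1L, 40), names(pc$status))
  expect_error(run_forest(pc$g, all1, seed = 1), "single phenotype class")
})

test_that("consensus retains only multi-forest SNPs, deterministically", {
  pc <- planted_cohort(137, n = 100, m = 200)
  c1 <- replicate_forests(pc$g, pc$status, n_forests = 8, n_trees = 25,
                          base_seed = 3, keep_models = FALSE)
  c2 <- replicate_forests(pc$g, pc$status, n_forests = 8, n_trees = 25,
                          base_seed = 3, keep_models = FALSE)
  expect_identical(c1$records, c2$records)
  expect_true(all(c1$records$forest_frequency >= 2))
  expect_true(all(c1$records$forest_frequency <= 8))
  # retention never exceeds the union of per-forest non-zero sets
  per_forest_union <- unique(unlist(lapply(1:8, function(f) {
    r <- run_forest(pc$g, pc$status, n_trees = 25, seed = 3 + f)
    names(r$vim_pct)[r$vim_pct > 0]
  })))
  expect_true(all(c1$records$snp_id %in% per_forest_union))
  expect_error(replicate_forests(pc$g, pc$status, n_forests = 1),
               "n_forests")
})

test_that("top-frequency flagging follows the order-statistic rule", {
  rec <- data.frame(snp_id = letters[1:5],
                    forest_frequency = c(2, 2, 3, 9, 19),
                    mean_vim_pct = 1:5,
                    region_of_interest = FALSE)
  out <- top_frequency_regions(rec)
  expect_identical(out$region_of_interest,
                   rec$forest_frequency >= 3)
  allsame <- transform(rec, forest_frequency = 4)
  expect_true(all(top_frequency_regions(allsame)$region_of_interest))
  single <- rec[1, ]
  expect_true(top_frequency_regions(single)$region_of_interest)
  expect_error(top_frequency_regions(rec[0, ]), "empty")
})

test_that("prediction errors behave sensibly on held-out animals", {
  pc <- planted_cohort(139, n = 120, m = 100)
  train_ids <- names(pc$status)[1:60]
  test_ids <- names(pc$status)[61:120]
  g_train <- subset_genotypes(pc$g, animals = train_ids)
  g_test <- subset_genotypes(pc$g, animals = test_ids)
  cons <- replicate_forests(g_train, pc$status, n_forests = 5,
                            n_trees = 25, base_seed = 11)
  err <- evaluate_prediction(cons, g_test, pc$status)
  # perfectly separable planted signal: low error throughout
  expect_lt(err["prediction", "overall"], 0.2)
  expect_lt(err["prediction", "class1"], 0.2)
  # flipping the test labels inverts the error rate
  flipped <- setNames(1L - pc$status[test_ids], test_ids)
  err_flip <- evaluate_prediction(cons, g_test, flipped)
  expect_equal(err_flip["prediction", "overall"],
               1 - err["prediction", "overall"], tolerance = 1e-12)
  expect_error(evaluate_prediction(cons,
                                   subset_genotypes(g_test, snps = 1:10),
                                   pc$status), "alignment")
  empty <- subset_genotypes(pc$g, animals = character(0))
  expect_error(evaluate_prediction(cons, empty, pc$status), "empty")
})

test_that("even class weighting narrows the per-class OOB gap vs unweighted", {
  # 90/10 imbalanced cohort with a weak minority-enriched signal: the
  # balanced forest must treat the minority class better than a plain
  # unweighted forest does (full parity is not attainable with so few
  # unique minority animals)
  gap <- function(pred, y) {
    abs(mean(pred[y == "0"] != "0", na.rm = TRUE) -
          mean(pred[y == "1"] != "1", na.rm = TRUE))
  }
  gaps <- vapply(1:5, function(s) {
    set.seed(150 + s)
    n <- 200
    dose <- sapply(runif(100, 0.1, 0.9), function(f) rbinom(n, 2, f))
    rownames(dose) <- sprintf("an%04d", seq_len(n))
    status <- setNames(c(rep(0L, 180), rep(1L, 20)), rownames(dose))
    for (j in 1:5) dose[status == 1L, j] <- rbinom(20, 2, 0.85)
    g <- genotype_matrix(dose, marker_map(sprintf("s%03d", 1:100),
                                          rep(1L, 100), 1:100 * 1000L))
    r <- run_forest(g, status, n_trees = 75, seed = s)
    y <- factor(status[animal_ids(g)], levels = c(0, 1))
    # unweighted reference forest on the same data and seed
    M <- spastigen:::rf_features(g)
    fu <- ranger::ranger(x = M, y = y, num.trees = 75, seed = s,
                         num.threads = 1)
    c(weighted = gap(r$model$predictions, y),
      unweighted = gap(fu$predictions, y))
  }, c(weighted = 0, unweighted = 0))
  expect_lt(mean(gaps["weighted", ]), mean(gaps["unweighted", ]))
})

test_that("intersection with the GQLS hits is an inner join", {
  rec <- data.frame(snp_id = c("a", "b", "c"),
                    forest_frequency = c(5, 4, 2),
                    mean_vim_pct = c(1, 2, 3))
  assoc <- data.frame(snp_id = c("b", "c", "d"), chromosome = 1,
                      position_bp = 1:3, p_value = c(0.001, 0.2, 0.003),
                      q_value = c(0.01, 0.5, 0.04), maf = 0.3)
  out <- intersect_with_gqls(rec, assoc)
  expect_setequal(out$snp_id, "b") # c fails q <= 0.10, d not in consensus
  none <- intersect_with_gqls(rec, transform(assoc, snp_id = c("x", "y", "z")))
  expect_equal(nrow(none), 0L)
  all_in <- intersect_with_gqls(
    rec, data.frame(snp_id = c("a", "b", "c"), chromosome = 1,
                    position_bp = 1:3, p_value = 0.001, q_value = 0.01,
                    maf = 0.3))
  expect_setequal(all_in$snp_id, c("a", "b", "c"))
  expect_true(all(c("forest_frequency", "mean_vim_pct", "q_value", "maf")
                  %in% names(all_in)))
})
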