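#' Simulation configuration for the synthetic study cohort
#'
#' The generator emulates the statistical structure of a pedigreed dairy-cattle
#' case-control cohort: 29 autosomes of 50K-density markers, strong paternal
#' half-sib family structure (few sires, many dams), a liability-threshold
#' disease architecture with a few QTL on a polygenic background with
#' underlying-scale heritability ~0.41, and a case prevalence near 59% in a
#' cohort of ~265 phenotyped animals split 40 (training) / 225 (testing).
#' Defaults reproduce that structure at marker densities small enough for
#' routine runs; `snps_per_chromosome` scales the map.
#'
#' @param n_chromosomes number of autosomes (default 29).
#' @param snps_per_chromosome markers per autosome.
#' @param chromosome_length_bp autosome length in bp.
#' @param n_founders number of founder animals.
#' @param n_generations generations bred below the founders.
#' @param offspring_per_mating offspring produced per dam per generation.
#' @param n_sires_per_generation sires in service each generation (small
#'   values give large half-sib families).
#' @param sire_fraction fraction of founders that are male.
#' @param founder_maf_range interval in (0, 0.5] from which each marker's
#'   founder minor-allele frequency is drawn.
#' @param n_crossovers crossovers per chromosome per meiosis.
#' @param n_qtl number of liability QTL planted among the markers.
#' @param qtl_effect_sd standard deviation of per-QTL allele-substitution
#'   effects, liability-scale standard deviations.
#' @param h2_underlying target underlying-scale heritability in `[0,1]`.
#' @param prevalence_target target case prevalence in (0,1).
#' @param n_phenotyped phenotyped cohort size (training + testing).
#' @param n_training training-set size.
#' @param missing_rate completely-at-random missing-genotype rate.
#' @param seed integer seed; fully determines all outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 29,
                       snps_per_chromosome = 40,
                       chromosome_length_bp = 1e8,
                       n_founders = 60,
                       n_generations = 2,
                       offspring_per_mating = 4,
                       n_sires_per_generation = 5,
                       sire_fraction = 0.15,
                       founder_maf_range = c(0.05, 0.5),
                       n_crossovers = 1,
                       n_qtl = 5,
                       qtl_effect_sd = 0.35,
                       h2_underlying = 0.41,
                       prevalence_target = 0.5925,
                       n_phenotyped = 265,
                       n_training = 40,
                       missing_rate = 0.01,
                       seed = 1) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_sires_per_generation = as.integer(n_sires_per_generation),
    sire_fraction = sire_fraction,
    founder_maf_range = founder_maf_range,
    n_crossovers = as.integer(n_crossovers),
    n_qtl = as.integer(n_qtl),
    qtl_effect_sd = qtl_effect_sd,
    h2_underlying = h2_underlying,
    prevalence_target = prevalence_target,
    n_phenotyped = as.integer(n_phenotyped),
    n_training = as.integer(n_training),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid sim_config field '", field, "': ", msg)
  }
  chk(cfg$n_chromosomes >= 1, "n_chromosomes", "must be >= 1")
  chk(cfg$snps_per_chromosome >= 1, "snps_per_chromosome", "must be >= 1")
  chk(cfg$n_founders >= 2, "n_founders", "must be >= 2")
  chk(cfg$n_generations >= 1, "n_generations", "must be >= 1")
  chk(cfg$offspring_per_mating >= 1, "offspring_per_mating", "must be >= 1")
  chk(length(cfg$founder_maf_range) == 2 &&
        cfg$founder_maf_range[1] > 0 && cfg$founder_maf_range[2] <= 0.5 &&
        cfg$founder_maf_range[1] <= cfg$founder_maf_range[2],
      "founder_maf_range", "must be an interval within (0, 0.5]")
  chk(cfg$h2_underlying >= 0 && cfg$h2_underlying <= 1,
      "h2_underlying", "must be in [0,1]")
  chk(cfg$prevalence_target > 0 && cfg$prevalence_target < 1,
      "prevalence_target", "must be in (0,1)")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate", "must be in [0,1)")
  chk(cfg$n_training >= 0 && cfg$n_training < cfg$n_phenotyped,
      "n_training", "must be < n_phenotyped")
  chk(cfg$n_qtl >= 0, "n_qtl", "must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a half-sib-structured pedigree
#'
#' Founders (generation 0) are split into a small male and a larger female
#' pool. Each later generation mates every available dam to one of
#' `n_sires_per_generation` sires drawn from the previous generation's males,
#' producing `offspring_per_mating` offspring per dam; the small sire pool
#' creates the large paternal half-sib families typical of AI-bred dairy
#' cattle. Parents always precede offspring in record order.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with extra columns `generation` and `sex`
#'   ("M"/"F").
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_m <- max(1L, round(config$n_founders * config$sire_fraction))
  if (config$n_founders - n_m < 1L) n_m <- config$n_founders - 1L
  sex <- c(rep("M", n_m), rep("F", config$n_founders - n_m))
  rec <- data.frame(
    animal = sprintf("G0_%04d", seq_len(config$n_founders)),
    sire = "0", dam = "0", generation = 0L, sex = sex,
    stringsAsFactors = FALSE
  )
  for (g in seq_len(config$n_generations)) {
    prev <- rec[rec$generation == g - 1L, ]
    sires <- prev$animal[prev$sex == "M"]
    dams <- prev$animal[prev$sex == "F"]
    if (!length(sires) || !length(dams)) {
      stop("generation ", g, " has no available ",
           if (!length(sires)) "sires" else "dams")
    }
    sires <- sires[seq_len(min(length(sires), config$n_sires_per_generation))]
    kid <- 0L
    rows <- vector("list", length(dams))
    for (di in seq_along(dams)) {
      s <- sample(sires, 1L)
      off <- vector("list", config$offspring_per_mating)
      for (o in seq_len(config$offspring_per_mating)) {
        kid <- kid + 1L
        off[[o]] <- data.frame(
          animal = sprintf("G%d_%04d", g, kid),
          sire = s, dam = dams[di], generation = g,
          sex = sample(c("M", "F"), 1L),
          stringsAsFactors = FALSE
        )
      }
      rows[[di]] <- do.call(rbind, off)
    }
    rec <- rbind(rec, do.call(rbind, rows))
  }
  p <- pedigree(rec$animal, rec$sire, rec$dam, reorder = FALSE)
  p$generation <- rec$generation
  p$sex <- rec$sex
  p
}

#' Simulate a marker map
#'
#' Markers are placed uniformly at random along each chromosome (positions
#' sorted, deduplicated) to emulate a fixed-density genotyping array.
#'
#' @param config a [sim_config()].
#' @return a [marker_map()].
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    pos <- sort(sample.int(config$chromosome_length_bp,
                           config$snps_per_chromosome))
    data.frame(
      snp_id = sprintf("snp_c%02d_%05d", chr, seq_along(pos)),
      chromosome = chr, position_bp = pos,
      stringsAsFactors = FALSE
    )
  })
  m <- do.call(rbind, maps)
  marker_map(m$snp_id, m$chromosome, m$position_bp,
             allele_a = rep("A", nrow(m)), allele_b = rep("B", nrow(m)))
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotype alleles are drawn per marker from a Bernoulli with the
#' marker's founder allele-B frequency (drawn from `founder_maf_range`).
#' Each non-founder inherits one gamete from each parent; a gamete is formed
#' per chromosome by sampling `n_crossovers` uniformly placed crossovers and
#' alternating between the parent's two haplotypes from a random start.
#' Dosage = number of B alleles; missing calls are injected completely at
#' random at `missing_rate`.
#'
#' @param ped a pedigree from [simulate_pedigree()] (or any [pedigree()] in
#'   which every animal has both parents known or both unknown).
#' @param map a [marker_map()].
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] covering every animal in the pedigree. The
#'   phased founder/descendant haplotypes are attached as attribute
#'   `haplotypes` (two 0/1 matrices), used by LD validation against phased
#'   truth.
#' @export
simulate_genotypes <- function(ped, map, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "marker_map"),
            inherits(config, "sim_config"))
  one_parent <- xor(ped$sire == "0", ped$dam == "0")
  if (any(one_parent)) {
    stop("animal(s) with exactly one known parent (need both or none): ",
         paste(ped$animal[one_parent], collapse = ", "))
  }
  set.seed(config$seed + 2L)
  n <- nrow(ped)
  m <- nrow(map)
  freq_b <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  h1 <- matrix(0L, n, m, dimnames = list(ped$animal, map$snp_id))
  h2 <- h1
  idx <- setNames(seq_len(n), ped$animal)
  chr_cols <- split(seq_len(m), map$chromosome)
  chr_pos <- split(map$position_bp, map$chromosome)

  gamete <- function(pa, pb) { # parent's two haplotype rows -> one gamete
    out <- integer(m)
    for (ci in seq_along(chr_cols)) {
      cols <- chr_cols[[ci]]
      pos <- chr_pos[[ci]]
      cuts <- sort(runif(config$n_crossovers, 0, config$chromosome_length_bp))
      seg <- findInterval(pos, cuts) # 0..n_crossovers
      use_a <- (seg + sample(0:1, 1L)) %% 2L == 0L
      out[cols] <- ifelse(use_a, pa[cols], pb[cols])
    }
    out
  }

  for (i in seq_len(n)) {
    if (ped$sire[i] == "0") {
      h1[i, ] <- rbinom(m, 1L, freq_b)
      h2[i, ] <- rbinom(m, 1L, freq_b)
    } else {
      s <- idx[[ped$sire[i]]]
      d <- idx[[ped$dam[i]]]
      h1[i, ] <- gamete(h1[s, ], h2[s, ])
      h2[i, ] <- gamete(h1[d, ], h2[d, ])
    }
  }
  dose <- h1 + h2
  if (config$missing_rate > 0) {
    drop <- runif(length(dose)) < config$missing_rate
    dose[drop] <- NA_integer_
  }
  g <- genotype_matrix(dose, map)
  attr(g, "haplotypes") <- list(h1 = h1, h2 = h2)
  g
}

#' Simulate case/control status under the liability-threshold model
#'
#' Liability is the sum of a QTL term (planted marker effects), a polygenic
#' effect consistent with the pedigree, and a unit-variance residual. The
#' polygenic variance is chosen jointly with the realized QTL variance so the
#' total genetic variance is `h2/(1-h2)` times the unit residual variance,
#' i.e. the underlying-scale heritability equals `h2_underlying`. An animal
#' is affected when its liability exceeds the empirical
#' `(1 - prevalence_target)` quantile of the cohort's realized liabilities,
#' guaranteeing the target case count up to integer rounding.
#'
#' @param ped pedigree (with both-or-neither parent rule).
#' @param g a [genotype_matrix()] covering the pedigree.
#' @param config a [sim_config()].
#' @param animals ids of the phenotyped subset (threshold is taken over
#'   these); default all genotyped animals.
#' @return a list with `status` (named 0/1 vector over `animals`),
#'   `realized_prevalence`, `liability` (named), `qtl` (data.frame of planted
#'   snp_id/index/effect), `sigma2_u`, `sigma2_qtl`.
#' @export
simulate_liability_phenotypes <- function(ped, g, config,
                                          animals = animal_ids(g)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  dose <- g$dosage
  hap <- attr(g, "haplotypes")
  # use the complete (pre-missingness) dosages for the truth if available
  if (!is.null(hap)) dose <- hap$h1 + hap$h2
  m <- ncol(dose)

  sigma2_g <- if (config$h2_underlying >= 1) Inf else
    config$h2_underlying / (1 - config$h2_underlying)
  qtl_idx <- integer(0)
  eff <- numeric(0)
  g_qtl <- setNames(rep(0, nrow(dose)), rownames(dose))
  if (config$n_qtl > 0 && config$h2_underlying > 0) {
    p <- colMeans(dose, na.rm = TRUE) / 2
    poly <- which(p > 0.1 & p < 0.9)
    if (length(poly) < config$n_qtl) {
      stop("not enough polymorphic markers to plant ", config$n_qtl, " QTL")
    }
    qtl_idx <- sort(sample(poly, config$n_qtl))
    eff <- rnorm(config$n_qtl, 0, config$qtl_effect_sd)
    g_qtl <- drop(dose[, qtl_idx, drop = FALSE] %*% eff)
    g_qtl <- g_qtl - mean(g_qtl)
  }
  v_qtl <- if (length(qtl_idx)) mean(g_qtl^2) else 0
  if (v_qtl > sigma2_g + 1e-12) {
    stop("configuration error: realized QTL variance (", signif(v_qtl, 3),
         ") exceeds the target genetic variance (", signif(sigma2_g, 3),
         "); reduce n_qtl or qtl_effect_sd")
  }
  sigma2_u <- max(sigma2_g - v_qtl, 0)

  u <- simulate_polygenic(ped, sigma2_u)
  e <- rnorm(nrow(dose))
  liab <- g_qtl[rownames(dose)] + u[rownames(dose)] + e
  names(liab) <- rownames(dose)

  liab_ph <- liab[animals]
  n <- length(liab_ph)
  n_cases <- round(config$prevalence_target * n)
  status <- setNames(integer(n), animals)
  if (n_cases > 0) {
    thr <- sort(liab_ph, decreasing = TRUE)[n_cases]
    status[liab_ph >= thr] <- 1L
  }
  list(
    status = status,
    realized_prevalence = mean(status),
    liability = liab_ph,
    qtl = data.frame(snp_id = colnames(dose)[qtl_idx], index = qtl_idx,
                     effect = eff, stringsAsFactors = FALSE),
    sigma2_u = sigma2_u,
    sigma2_qtl = v_qtl
  )
}

# Polygenic effects by the pedigree cascade: founders ~ N(0, s2u); offspring
# u = (u_s + u_d)/2 + Mendelian-sampling term with variance
# s2u * (0.5 - 0.25 (F_s + F_d)), exactly consistent with the A-matrix.
simulate_polygenic <- function(ped, sigma2_u) {
  n <- nrow(ped)
  u <- setNames(numeric(n), ped$animal)
  if (sigma2_u <= 0) return(u)
  Fi <- inbreeding(ped)$F
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == "0" && d == "0") {
      u[i] <- rnorm(1, 0, sqrt(sigma2_u))
    } else {
      fs <- if (s == "0") 0 else Fi[[s]]
      fd <- if (d == "0") 0 else Fi[[d]]
      us <- if (s == "0") rnorm(1, 0, sqrt(sigma2_u)) else u[[s]]
      ud <- if (d == "0") rnorm(1, 0, sqrt(sigma2_u)) else u[[d]]
      vm <- sigma2_u * (0.5 - 0.25 * (fs + fd))
      u[i] <- 0.5 * (us + ud) + rnorm(1, 0, sqrt(vm))
    }
  }
  u
}

#' Simulate a complete study cohort
#'
#' Runs [simulate_pedigree()], [simulate_marker_map()],
#' [simulate_genotypes()] and [simulate_liability_phenotypes()] under one
#' seed and assembles the phenotyped cohort: the most recent generation's
#' animals are sampled down to `n_phenotyped`, of which `n_training` form the
#' training set and the rest the testing set.
#'
#' @param config a [sim_config()].
#' @return a list of class `cohort_bundle`: `pedigree`, `map`, `genotypes`
#'   (phenotyped animals only), `genotypes_all`, `phenotypes` (named 0/1),
#'   `true_qtl`, `true_h2_underlying`, `realized_prevalence`,
#'   `training_ids`, `testing_ids`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  map <- simulate_marker_map(config)
  g_all <- simulate_genotypes(ped, map, config)

  set.seed(config$seed + 4L)
  pool <- ped$animal[ped$generation == max(ped$generation)]
  if (length(pool) < config$n_phenotyped) {
    stop("last generation has ", length(pool), " animals; need n_phenotyped = ",
         config$n_phenotyped, " (increase founders/offspring_per_mating)")
  }
  phen_ids <- sort(sample(pool, config$n_phenotyped))
  train <- sort(sample(phen_ids, config$n_training))
  test <- setdiff(phen_ids, train)

  ph <- simulate_liability_phenotypes(ped, g_all, config, animals = phen_ids)
  bundle <- list(
    pedigree = ped,
    map = map,
    genotypes = subset_genotypes(g_all, animals = phen_ids),
    genotypes_all = g_all,
    phenotypes = ph$status,
    liability = ph$liability,
    true_qtl = ph$qtl,
    true_h2_underlying = config$h2_underlying,
    realized_prevalence = ph$realized_prevalence,
    training_ids = train,
    testing_ids = test,
    config = config
  )
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", length(x$phenotypes), "phenotyped animals (",
      sum(x$phenotypes == 1L), "affected /", sum(x$phenotypes == 0L),
      "unaffected ), prevalence",
      sprintf("%.2f%%", 100 * x$realized_prevalence), "\n")
  cat("  pedigree:", nrow(x$pedigree), "animals;",
      nrow(x$map), "SNPs on", length(unique(x$map$chromosome)),
      "chromosomes;", nrow(x$true_qtl), "planted QTL\n")
  cat("  training:", length(x$training_ids), " testing:",
      length(x$testing_ids), "\n")
  invisible(x)
}

#' Cohort phenotype summary
#'
#' Case/control counts and prevalence of a phenotype vector, the summary
#' used in cohort reports (affected, unaffected, total, prevalence %).
#'
#' @param status named 0/1 status vector.
#' @return list with `n_affected`, `n_unaffected`, `n_total`,
#'   `prevalence_pct`.
#' @export
cohort_summary <- function(status) {
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)
  list(
    n_affected = n1,
    n_unaffected = n0,
    n_total = n1 + n0,
    prevalence_pct = 100 * n1 / (n1 + n0)
  )
}

#' Write a cohort to disk (PLINK text + CSVs + truth JSON)
#'
#' Writes `<prefix>.ped` / `<prefix>.map` (phenotyped animals),
#' `<prefix>_pedigree.csv`, `<prefix>_phenotypes.csv`,
#' `<prefix>_training_ids.txt`, `<prefix>_testing_ids.txt`,
#' `<prefix>_genes.bed` (synthetic gene intervals planted around each QTL)
#' and `<prefix>_truth.json` (QTL indices/effects, true underlying h2).
#'
#' @param bundle a `cohort_bundle`.
#' @param prefix output path prefix.
#' @param gene_halfwidth_bp half-width of each planted synthetic gene.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, prefix, gene_halfwidth_bp = 150000) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  files <- c(
    ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"),
    pedigree = paste0(prefix, "_pedigree.csv"),
    phen = paste0(prefix, "_phenotypes.csv"),
    train = paste0(prefix, "_training_ids.txt"),
    test = paste0(prefix, "_testing_ids.txt"),
    genes = paste0(prefix, "_genes.bed"),
    truth = paste0(prefix, "_truth.json")
  )
  write_plink_text(bundle$genotypes, prefix, status = bundle$phenotypes)
  write_pedigree(bundle$pedigree, files[["pedigree"]])
  write_phenotypes(bundle$phenotypes, files[["phen"]])
  writeLines(bundle$training_ids, files[["train"]])
  writeLines(bundle$testing_ids, files[["test"]])

  map <- bundle$map
  if (nrow(bundle$true_qtl)) {
    qm <- map[match(bundle$true_qtl$snp_id, map$snp_id), ]
    bed <- data.frame(
      chrom = qm$chromosome,
      start = pmax(qm$position_bp - gene_halfwidth_bp - 1L, 0L), # 0-based
      end = qm$position_bp + gene_halfwidth_bp,
      name = sprintf("SYNGENE_%02d", seq_len(nrow(qm)))
    )
    write.table(bed, files[["genes"]], sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  } else {
    file.create(files[["genes"]])
  }
  jsonlite::write_json(
    list(qtl = bundle$true_qtl,
         true_h2_underlying = bundle$true_h2_underlying,
         realized_prevalence = bundle$realized_prevalence,
         seed = bundle$config$seed),
    files[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(files)
}
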