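# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# n x m dosage matrix with named rows, uniform allele frequencies
random_genotypes <- function(seed, n = 100, m = 50, chrom = 1L,
                             freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  dose <- sapply(freq, function(f) rbinom(n, 2, f))
  rownames(dose) <- sprintf("an%04d", seq_len(n))
  map <- marker_map(sprintf("s%05d", seq_len(m)), rep(chrom, m),
                    seq_len(m) * 1000L)
  genotype_matrix(dose, map)
}

# case-control cohort with one fully informative SNP among noise
planted_cohort <- function(seed, n = 200, m = 1000, planted = m %/% 2) {
  set.seed(seed)
  status <- setNames(rep(c(0L, 1L), each = n / 2)[sample(n)],
                     sprintf("an%04d", seq_len(n)))
  dose <- matrix(rbinom(n * m, 2, 0.3), n, m,
                 dimnames = list(names(status), NULL))
  dose[, planted] <- ifelse(status == 1L, 2L, 0L)
  map <- marker_map(sprintf("s%05d", seq_len(m)), rep(1L, m),
                    seq_len(m) * 1000L)
  list(g = genotype_matrix(dose, map), status = status, planted = planted)
}

# paternal half-sib cohort with liability phenotype and block-diagonal A
halfsib_liability <- function(seed, fam = 100, off = 20, h2 = 0.4,
                              prevalence = 0.5) {
  set.seed(seed)
  s2u <- h2 / (1 - h2)
  n <- fam * off
  us <- rnorm(fam, 0, sqrt(s2u))
  u <- rep(us, each = off) / 2 + rnorm(n, 0, sqrt(0.75 * s2u))
  liab <- u + rnorm(n)
  thr <- sort(liab, decreasing = TRUE)[round(prevalence * n)]
  status <- setNames(as.integer(liab >= thr), sprintf("o%05d", seq_len(n)))
  blk <- matrix(0.25, off, off)
  diag(blk) <- 1
  A <- Matrix::bdiag(replicate(fam, blk, simplify = FALSE))
  dimnames(A) <- list(names(status), names(status))
  list(status = status, A = A, liability = liab)
}

# Wright's path-counting relationship oracle: a_ij = sum over common
# ancestors C and ancestor-paths P1 (C->i), P2 (C->j) meeting only at C of
# (1/2)^(len(P1)+len(P2)) * (1 + F_C), with F computed recursively as half
# the path-counted relationship of the parents. Exponential; fixtures only.
path_count_A <- function(ped) {
  ped <- pedigree(ped$animal, ped$sire, ped$dam)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  parents <- function(i) {
    out <- c(ped$sire[i], ped$dam[i])
    out[out != "0"]
  }
  # all ancestor paths i -> root fragments: list of vectors of animal indices
  paths_up <- function(i) {
    res <- list(i)
    for (p in parents(i)) {
      for (pp in paths_up(idx[[p]])) res <- c(res, list(c(i, pp)))
    }
    res
  }
  Fcoef <- function(i) {
    pa <- parents(i)
    if (length(pa) < 2) return(0)
    0.5 * rel(idx[[pa[1]]], idx[[pa[2]]])
  }
  rel <- function(i, j) {
    pi_ <- paths_up(i)
    pj_ <- paths_up(j)
    tot <- 0
    for (p1 in pi_) for (p2 in pj_) {
      ca <- p1[length(p1)]
      if (ca != p2[length(p2)]) next
      # paths must share only the common ancestor
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
      tot <- tot + 0.5^(length(p1) + length(p2) - 2) * (1 + Fcoef(ca))
    }
    tot
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- rel(i, j)
  }
  A
}

# random valid pedigree of n animals for oracle comparisons
random_pedigree <- function(seed, n = 8) {
  set.seed(seed)
  animal <- sprintf("p%02d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in 3:n) {
    if (runif(1) < 0.7 && i > 3) {
      pick <- sample(seq_len(i - 1), 2)
      sire[i] <- animal[pick[1]]
      dam[i] <- animal[pick[2]]
    }
  }
  pedigree(animal, sire, dam)
}

# exhaustive solid-spine oracle: validity straight from the definition,
# leftmost-start maximal blocks, non-overlapping
oracle_spine_blocks <- function(L, thr) {
  m <- nrow(L)
  valid <- function(i, j) {
    if (j <= i) return(FALSE)
    for (k in (i + 1):j) if (is.na(L[i, k]) || L[i, k] < thr) return(FALSE)
    for (k in i:(j - 1)) if (is.na(L[k, j]) || L[k, j] < thr) return(FALSE)
    TRUE
  }
  blocks <- list()
  i <- 1L
  while (i < m) {
    jbest <- 0L
    for (j in (i + 1L):m) if (valid(i, j)) jbest <- j
    if (jbest > 0L) {
      blocks[[length(blocks) + 1L]] <- c(i, jbest)
      i <- jbest + 1L
    } else i <- i + 1L
  }
  blocks
}

# phased two-locus fixture: haplotypes drawn from a strong-LD two-locus
# distribution (|D'| in [0.65, 1]), paired at random into unphased
# genotypes; returns the genotypes and the underlying phased alleles
phased_pair_fixture <- function(n = 5000) {
  pA <- runif(1, 0.1, 0.9)
  pB <- runif(1, 0.1, 0.9)
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- runif(1, 0.65, 1) * dmax
  h <- c((1 - pA) * (1 - pB) + D, (1 - pA) * pB - D,
         pA * (1 - pB) - D, pA * pB + D)
  idx <- sample(4, 2 * n, TRUE, prob = h)
  a <- c(0, 0, 1, 1)[idx]
  b <- c(0, 1, 0, 1)[idx]
  list(gi = a[1:n] + a[(n + 1):(2 * n)],
       gj = b[1:n] + b[(n + 1):(2 * n)],
       a = a, b = b)
}
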