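#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds Wright's additive relationship matrix A from a pedigree with the
#' standard tabular recursion over a topologically sorted pedigree:
#' `a_ii = 1 + 0.5 * a_sd` (s,d the parents of i; the cross term is 0 when
#' either parent is unknown) and `a_ij = 0.5 * (a_js + a_jd)` for each
#' earlier animal j. The diagonal is `1 + F_i` with `F_i` the inbreeding
#' coefficient; founders have diagonal exactly 1. An animal recorded with a
#' single known parent is treated as (known parent, unknown).
#'
#' @param ped a [pedigree()] (any record order; sorted internally).
#' @param ids optional ids to which the returned matrix is restricted
#'   (relationships are still computed on the full pedigree).
#' @return object of class `additive_relationship`: list with `ids` and the
#'   symmetric matrix `A` (dimnames = ids).
#' @export
build_A <- function(ped, ids = NULL) {
  if (!inherits(ped, "pedigree")) {
    ped <- pedigree(ped$animal, ped$sire, ped$dam)
  } else {
    ped <- pedigree(ped$animal, ped$sire, ped$dam) # re-sort defensively
  }
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[js, s] else rep(0, i - 1L)
      ad_ <- if (d > 0L) A[js, d] else rep(0, i - 1L)
      aij <- 0.5 * (as_ + ad_)
      A[js, i] <- aij
      A[i, js] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$animal)
    if (length(miss)) {
      stop("id(s) not in pedigree: ", paste(miss, collapse = ", "))
    }
    A <- A[ids, ids, drop = FALSE]
  } else {
    ids <- ped$animal
  }
  structure(list(ids = ids, A = A), class = "additive_relationship")
}

#' @export
print.additive_relationship <- function(x, ...) {
  Fb <- diag(x$A) - 1
  cat("additive_relationship:", length(x$ids), "animals; mean F =",
      sprintf("%.4f", mean(Fb)), "; inbred animals:", sum(Fb > 1e-12), "\n")
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes `F_i = a_ii - 1` for every animal without materializing the full
#' relationship matrix, using the L-matrix / D-vector decomposition
#' `A = L D L'` of Meuwissen and Luo: each animal's diagonal is accumulated
#' by tracing its ancestor contributions `l^2 d`. The mean coefficient is
#' reported both over inbred animals only (F > 0) and over all animals, the
#' two readings of a pedigree-wide "average inbreeding" summary.
#'
#' @param ped a [pedigree()].
#' @return list with `F` (named vector), `mean_F_inbred`, `mean_F_all`,
#'   `n_inbred`.
#' @export
inbreeding <- function(ped) {
  if (!inherits(ped, "pedigree") ||
      !identical(order(pedigree_toposort(ped)), seq_len(nrow(ped)))) {
    ped <- pedigree(ped$animal, ped$sire, ped$dam)
  }
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- as.integer(ifelse(ped$sire == "0", 0L, idx[ped$sire]))
  di <- as.integer(ifelse(ped$dam == "0", 0L, idx[ped$dam]))
  Fv <- numeric(n)
  Dv <- numeric(n) # within-family (Mendelian sampling) variance
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    fs <- if (s > 0L) Fv[s] else -1 # convention: unknown parent F = -1
    fd <- if (d > 0L) Fv[d] else -1
    Dv[i] <- 0.5 - 0.25 * (fs + fd) # 1 when both parents unknown
    # trace ancestor contributions of animal i: a_ii = sum l_ik^2 d_k
    l <- numeric(i)
    l[i] <- 1
    aii <- 0
    for (k in i:1) {
      if (l[k] == 0) next
      aii <- aii + l[k]^2 * Dv[k]
      if (si[k] > 0L) l[si[k]] <- l[si[k]] + 0.5 * l[k]
      if (di[k] > 0L) l[di[k]] <- l[di[k]] + 0.5 * l[k]
    }
    Fv[i] <- aii - 1
  }
  names(Fv) <- ped$animal
  inbred <- Fv > 1e-12
  list(
    F = Fv,
    mean_F_inbred = if (any(inbred)) mean(Fv[inbred]) else 0,
    mean_F_all = mean(Fv),
    n_inbred = sum(inbred)
  )
}

#' Kinship matrix for the association scan
#'
#' The working correlation handed to the GQLS test: by default the
#' pedigree-based A-submatrix of the genotyped animals; alternatively a
#' (VanRaden) genomic relationship matrix computed from the genotypes
#' themselves.
#'
#' @param ped a [pedigree()] (used when `method = "pedigree"`).
#' @param g a [genotype_matrix()]; its animal ids define the matrix order.
#' @param method `"pedigree"` (default) or `"genomic"`.
#' @return symmetric matrix with dimnames = `animal_ids(g)`.
#' @export
kinship_matrix <- function(ped, g, method = c("pedigree", "genomic")) {
  method <- match.arg(method)
  ids <- animal_ids(g)
  if (method == "pedigree") {
    build_A(ped, ids = ids)$A
  } else {
    grm(g)
  }
}

# VanRaden genomic relationship matrix (method 1), mean-imputed missing.
grm <- function(g) {
  M <- g$dosage
  p <- colMeans(M, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(M, 2, 2 * p)
  for (j in seq_len(ncol(Z))) {
    nas <- is.na(Z[, j])
    if (any(nas)) Z[nas, j] <- 0
  }
  G <- tcrossprod(Z) / sum(2 * p * (1 - p))
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Write an additive relationship matrix
#'
#' @param ar an `additive_relationship`.
#' @param path output file.
#' @param format `"dense"` (tab-separated matrix with ids) or `"triplet"`
#'   (id_i, id_j, a_ij for the nonzero upper triangle).
#' @return invisibly, `path`.
#' @export
write_A <- function(ar, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    out <- data.frame(id = ar$ids, ar$A, check.names = FALSE)
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    ut <- which(upper.tri(ar$A, diag = TRUE) & ar$A != 0, arr.ind = TRUE)
    out <- data.frame(
      id_i = ar$ids[ut[, 1]], id_j = ar$ids[ut[, 2]],
      a = ar$A[ut]
    )
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
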