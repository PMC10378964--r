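#' Marker map constructor
#'
#' A marker map records, for each SNP, its identifier, autosome (1-29 for the
#' bovine genome), 1-based physical position, and the two allele labels.
#' `allele_b` is the counted allele: the dosage stored in a
#' [genotype_matrix()] is the number of copies of `allele_b`.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome integer vector of autosome numbers.
#' @param position_bp integer vector of 1-based physical positions; must be
#'   strictly increasing within each chromosome.
#' @param allele_a,allele_b single-character allele labels (`allele_b` may be
#'   `NA` for SNPs where only one allele was ever observed).
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(snp_id, chromosome, position_bp,
                       allele_a = rep("A", length(snp_id)),
                       allele_b = rep("B", length(snp_id))) {
  if (anyDuplicated(snp_id)) {
    stop("duplicated snp_id in marker map")
  }
  chromosome <- as.integer(chromosome)
  if (any(is.na(chromosome)) || any(chromosome < 1L)) {
    stop("chromosome must be a positive integer")
  }
  m <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = chromosome,
    position_bp = as.integer(position_bp),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b),
    stringsAsFactors = FALSE
  )
  for (chr in unique(m$chromosome)) {
    pos <- m$position_bp[m$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Genotype matrix constructor
#'
#' Genotypes are stored as an animals x SNPs integer dosage matrix with codes
#' 0/1/2 (copies of the counted allele, `allele_b` of the map) and `NA` for
#' missing calls. Dosage/2 is the allelic proportion used by the GQLS scan.
#'
#' @param dosage integer matrix, rows = animals (rownames = animal ids),
#'   columns = SNPs (colnames = SNP ids, matching `map$snp_id`).
#' @param map a [marker_map()].
#' @return an object of class `genotype_matrix` with elements `dosage` and
#'   `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " columns but map has ", nrow(map),
         " SNPs")
  }
  if (is.null(rownames(dosage))) {
    stop("dosage must have animal ids as rownames")
  }
  colnames(dosage) <- map$snp_id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosage codes must be 0, 1, 2 or NA")
  }
  storage.mode(dosage) <- "integer"
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat("genotype_matrix:", nrow(d), "animals x", ncol(d), "SNPs on",
      length(unique(x$map$chromosome)), "chromosome(s)\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Animal identifiers of a genotype matrix
#' @param g a [genotype_matrix()].
#' @return character vector of animal ids (row order).
#' @export
animal_ids <- function(g) rownames(g$dosage)

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param animals optional character vector of animal ids (or logical/integer
#'   row index) to keep, in the order given.
#' @param snps optional character vector of SNP ids (or logical/integer
#'   column index) to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(g, animals = NULL, snps = NULL) {
  d <- g$dosage
  map <- g$map
  if (!is.null(animals)) {
    if (is.character(animals) && !all(animals %in% rownames(d))) {
      stop("unknown animal id(s): ",
           paste(setdiff(animals, rownames(d)), collapse = ", "))
    }
    d <- d[animals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      idx <- match(snps, map$snp_id)
      if (anyNA(idx)) {
        stop("unknown SNP id(s): ",
             paste(snps[is.na(idx)], collapse = ", "))
      }
    } else {
      idx <- seq_len(ncol(d))[snps]
    }
    d <- d[, idx, drop = FALSE]
    map <- map[idx, , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
  }
  structure(list(dosage = d, map = map), class = "genotype_matrix")
}

#' Pedigree constructor
#'
#' @param animal,sire,dam vectors of ids; `0`, `""` or `NA` mark an unknown
#'   parent. An animal with exactly one known parent is allowed here (the
#'   relationship machinery treats the missing parent as unknown) but the
#'   gene-dropping simulator requires both or neither.
#' @param reorder sort records topologically (parents before offspring)?
#' @return a `data.frame` of class `pedigree` with character columns
#'   `animal`, `sire`, `dam` ("0" = unknown), parents preceding offspring.
#' @export
pedigree <- function(animal, sire, dam, reorder = TRUE) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- "0"
    x
  }
  p <- data.frame(
    animal = as.character(animal),
    sire = norm(sire),
    dam = norm(dam),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(p$animal)) {
    stop("duplicated animal id(s) in pedigree: ",
         paste(unique(p$animal[duplicated(p$animal)]), collapse = ", "))
  }
  if (any(p$animal == "0")) stop("'0' is reserved for unknown parents")
  # parents referenced but absent become implicit founders
  parents <- setdiff(unique(c(p$sire, p$dam)), c("0", p$animal))
  if (length(parents)) {
    p <- rbind(
      data.frame(animal = parents, sire = "0", dam = "0",
                 stringsAsFactors = FALSE),
      p
    )
  }
  ord <- pedigree_toposort(p)
  if (reorder) p <- p[ord, , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("pedigree", "data.frame")
  p
}

# Topological order of a pedigree; errors listing a cycle if one exists.
pedigree_toposort <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n)
  names(idx) <- p$animal
  si <- ifelse(p$sire == "0", NA_integer_, idx[p$sire])
  di <- ifelse(p$dam == "0", NA_integer_, idx[p$dam])
  state <- integer(n) # 0 unseen, 1 on stack, 2 done
  ord <- integer(0)
  visit <- function(i, path) {
    if (state[i] == 1L) {
      cyc <- c(path[which(path == i)[1]:length(path)], i)
      stop("pedigree cycle detected: ",
           paste(p$animal[cyc], collapse = " -> "))
    }
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (par in c(si[i], di[i])) {
      if (!is.na(par)) visit(par, c(path, i))
    }
    state[i] <<- 2L
    ord <<- c(ord, i)
    invisible()
  }
  for (i in seq_len(n)) if (state[i] == 0L) visit(i, integer(0))
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(x$sire == "0" & x$dam == "0")
  cat("pedigree:", nrow(x), "animals (", founders, "founders,",
      length(unique(x$sire[x$sire != "0"])), "sires,",
      length(unique(x$dam[x$dam != "0"])), "dams )\n")
  invisible(x)
}

#' Read / write a pedigree CSV (animal,sire,dam; 0 = unknown)
#' @param path file path.
#' @return for the reader, a [pedigree()].
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(d))) {
    stop("pedigree CSV needs columns animal,sire,dam")
  }
  pedigree(d$animal, d$sire, d$dam)
}

#' @rdname read_pedigree
#' @param p a [pedigree()].
#' @export
write_pedigree <- function(p, path) {
  write.table(as.data.frame(p)[, c("animal", "sire", "dam")], path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV (animal,status)
#'
#' Status must be coded 0 = unaffected, 1 = affected. PLINK-style 1/2 coding
#' (1 = control, 2 = case) is auto-detected (values are exactly {1,2}) and
#' mapped to 0/1 with a warning.
#'
#' @param path file path.
#' @return named integer vector of 0/1 statuses, names = animal ids.
#' @export
read_phenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",",
                  colClasses = c("character", "integer"))
  if (ncol(d) < 2) stop("phenotype CSV needs columns animal,status")
  status <- d[[2]]
  if (all(status %in% c(1L, 2L)) && any(status == 2L)) {
    warning("phenotypes look PLINK-coded (1/2); remapping to 0/1")
    status <- status - 1L
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("status must be 0 (unaffected) or 1 (affected)")
  }
  setNames(status, d[[1]])
}

#' @rdname read_phenotypes
#' @param status named 0/1 vector.
#' @export
write_phenotypes <- function(status, path) {
  write.table(data.frame(animal = names(status), status = as.integer(status)),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
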