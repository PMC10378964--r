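#' Read PLINK text genotypes (.ped / .map)
#'
#' Parses a PLINK pedigree text fileset into a [genotype_matrix()]. Each
#' `.ped` row is `FID IID PAT MAT SEX PHENO` followed by two allele calls per
#' SNP; `0 0` is a missing call. The counted allele (`allele_b`, dosage 2)
#' of each SNP is the second distinct allele encountered in file order;
#' monomorphic-in-file SNPs get `allele_b = NA` and dosage 0. The `.ped`
#' phenotype column is ignored (phenotypes come from the phenotype CSV).
#' `.map` may have 3 (chr, id, bp) or 4 (chr, id, cM, bp) columns.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_matrix()]; animal ids are the IID column.
#' @export
read_plink_text <- function(ped_path, map_path) {
  mp <- read.table(map_path, header = FALSE, colClasses = "character")
  if (!ncol(mp) %in% c(3L, 4L)) {
    stop(".map must have 3 or 4 columns, found ", ncol(mp))
  }
  pos_col <- ncol(mp)
  chrom <- as.integer(mp[[1]])
  snp_id <- mp[[2]]
  pos <- as.integer(mp[[pos_col]])
  m <- nrow(mp)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("ragged .ped row(s) ", paste(which(lens != want), collapse = ", "),
         ": expected ", want, " fields")
  }
  n <- length(toks)
  ids <- vapply(toks, `[[`, "", 2L)
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    al <- toks[[i]][-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, 2L)]
  }

  dose <- matrix(NA_integer_, n, m, dimnames = list(ids, snp_id))
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    c1 <- a1[, j]; c2 <- a2[, j]
    miss <- c1 == "0" | c2 == "0"
    obs <- unique(c(rbind(c1[!miss], c2[!miss]))) # file order, interleaved
    if (length(obs) > 2L) {
      stop("non-biallelic SNP '", snp_id[j], "': alleles ",
           paste(obs, collapse = ", "))
    }
    if (length(obs) >= 1L) allele_a[j] <- obs[1L]
    if (length(obs) == 2L) allele_b[j] <- obs[2L]
    dj <- (c1 == allele_b[j]) + (c2 == allele_b[j])
    if (is.na(allele_b[j])) dj <- rep(0L, n)
    dj[miss] <- NA_integer_
    dose[, j] <- dj
  }
  map <- marker_map(snp_id, chrom, pos, allele_a = allele_a,
                    allele_b = allele_b)
  genotype_matrix(dose, map)
}

#' Write PLINK text genotypes (.ped / .map)
#'
#' @param g a [genotype_matrix()].
#' @param prefix output prefix (writes `<prefix>.ped` and `<prefix>.map`).
#' @param status optional named 0/1 status vector written to the .ped
#'   phenotype column in PLINK 1/2 coding; animals without status get -9.
#' @return invisibly, the two paths.
#' @export
write_plink_text <- function(g, prefix, status = NULL) {
  map <- g$map
  mp <- data.frame(chr = map$chromosome, id = map$snp_id, cm = 0,
                   bp = map$position_bp)
  write.table(mp, paste0(prefix, ".map"), sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)

  d <- g$dosage
  aa <- ifelse(is.na(map$allele_a), "A", map$allele_a)
  ab <- ifelse(is.na(map$allele_b), "B", map$allele_b)
  n <- nrow(d); m <- ncol(d)
  ph <- rep(-9L, n)
  if (!is.null(status)) {
    hit <- match(rownames(d), names(status))
    ph[!is.na(hit)] <- as.integer(status[hit[!is.na(hit)]]) + 1L
  }
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    di <- d[i, ]
    c1 <- ifelse(is.na(di), "0", ifelse(di >= 1L, ab, aa))
    c2 <- ifelse(is.na(di), "0", ifelse(di == 2L, ab, aa))
    calls <- as.vector(rbind(c1, c2))
    writeLines(paste(c(rownames(d)[i], rownames(d)[i], "0", "0", "0",
                       ph[i], calls), collapse = " "), con)
  }
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read a minimal VCF into a genotype matrix
#'
#' Supports plain-text, uncompressed VCF with a GT field (phased or
#' unphased); only biallelic records are accepted. Dosage counts the ALT
#' allele (`allele_b` = ALT).
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("VCF has no variant records")
  toks <- strsplit(body, "\t")
  m <- length(toks)
  n <- length(samples)
  dose <- matrix(NA_integer_, n, m)
  chrom <- integer(m); pos <- integer(m); id <- character(m)
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    tk <- toks[[j]]
    if (length(tk) != 9L + n) stop("ragged VCF record ", j)
    if (grepl(",", tk[5])) {
      stop("non-biallelic VCF record '", tk[3], "' (ALT = ", tk[5], ")")
    }
    chrom[j] <- as.integer(sub("^[Cc]hr", "", tk[1]))
    pos[j] <- as.integer(tk[2])
    id[j] <- if (tk[3] == ".") paste0("var_", tk[1], "_", tk[2]) else tk[3]
    ref[j] <- tk[4]; alt[j] <- tk[5]
    fmt <- strsplit(tk[9], ":")[[1]]
    gt_i <- which(fmt == "GT")
    if (!length(gt_i)) stop("record '", id[j], "' has no GT field")
    gt <- vapply(strsplit(tk[-(1:9)], ":"), `[[`, "", gt_i[1])
    al <- strsplit(gt, "[/|]")
    dose[, j] <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, 0L)
  }
  map <- marker_map(id, chrom, pos, allele_a = ref, allele_b = alt)
  rownames(dose) <- samples
  genotype_matrix(dose, map)
}

#' Read gene annotation (BED or GFF3)
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates; GFF3 is already 1-based inclusive and rows with
#' `type == "gene"` are used when present (all rows otherwise). Malformed
#' rows are skipped, with the skip count attached as attribute
#' `n_skipped`.
#'
#' @param path annotation file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame with columns `gene_id`, `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  skipped <- 0L
  rows <- list()
  if (format == "bed") {
    for (ln in lines) {
      tk <- strsplit(ln, "\t")[[1]]
      chr <- suppressWarnings(as.integer(sub("^[Cc]hr", "", tk[1])))
      s <- suppressWarnings(as.integer(tk[2]))
      e <- suppressWarnings(as.integer(tk[3]))
      if (length(tk) < 3L || is.na(chr) || is.na(s) || is.na(e) || s >= e) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = if (length(tk) >= 4L) tk[4] else paste0("gene_", chr, "_", s),
        chromosome = chr, start_bp = s + 1L, end_bp = e,
        stringsAsFactors = FALSE
      )
    }
  } else {
    recs <- strsplit(lines, "\t")
    types <- vapply(recs, function(tk) if (length(tk) >= 3L) tk[3] else "",
                    "")
    if (any(types == "gene")) recs <- recs[types == "gene"]
    for (tk in recs) {
      chr <- suppressWarnings(as.integer(sub("^[Cc]hr", "", tk[1])))
      s <- suppressWarnings(as.integer(tk[4]))
      e <- suppressWarnings(as.integer(tk[5]))
      if (length(tk) < 9L || is.na(chr) || is.na(s) || is.na(e) || s > e) {
        skipped <- skipped + 1L
        next
      }
      attr_id <- regmatches(tk[9], regexpr("(ID|Name|gene_id)=[^;]+", tk[9]))
      gid <- if (length(attr_id)) sub("^[^=]+=", "", attr_id[1]) else
        paste0("gene_", chr, "_", s)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, chromosome = chr, start_bp = s, end_bp = e,
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped) {
    warning(skipped, " malformed annotation row(s) skipped")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), chromosome = integer(),
               start_bp = integer(), end_bp = integer())
  attr(out, "n_skipped") <- skipped
  out
}
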