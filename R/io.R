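# Genotype, phenotype, pedigree and results I/O. Genotype codes are counts
# of allele "2" (0/1/2, NA missing); heterozygote phase is never
# represented. Coordinates are 1-based base pairs as in .map/.bim files.

#' Construct a genotype matrix
#'
#' @param codes integer matrix, individuals x SNPs, entries 0/1/2/`NA`
#'   (count of allele "2").
#' @param map data frame with columns `snp_id`, `chr`, `pos` and optionally
#'   `allele1`, `allele2`; one row per column of `codes`.
#' @param ids character vector of individual ids, one per row of `codes`.
#' @return Object of class `genotype_matrix` (list: `ids`, `map`, `codes`).
#' @export
genotype_matrix <- function(codes, map, ids) {
  codes <- as.matrix(codes)
  stopifnot(nrow(map) == ncol(codes), length(ids) == nrow(codes),
            all(codes %in% c(0:2, NA)))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stopifnot(all(map$pos >= 1))
  if (!"allele1" %in% names(map)) map$allele1 <- "1"
  if (!"allele2" %in% names(map)) map$allele2 <- "2"
  map$snp_id <- as.character(map$snp_id)
  map$chr <- as.character(map$chr)
  dimnames(codes) <- list(ids, map$snp_id)
  structure(list(ids = as.character(ids), map = map, codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      nrow(x$map), "SNPs on", length(unique(x$map$chr)), "chromosome(s)\n")
  invisible(x)
}

#' Per-SNP minor allele frequency
#'
#' Computed from non-missing codes; the allele-"2" frequency clipped at 0.5.
#' @param geno a `genotype_matrix`.
#' @return Named numeric vector.
#' @export
snp_maf <- function(geno) {
  p2 <- colMeans(geno$codes, na.rm = TRUE) / 2
  stats::setNames(pmin(p2, 1 - p2), geno$map$snp_id)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains exactly the SNPs whose MAF (on non-missing codes) is at least
#' `threshold`, preserving the original SNP order. Idempotent.
#'
#' @param geno a `genotype_matrix`.
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.05).
#' @return The filtered `genotype_matrix`; warns if no SNP survives.
#' @export
filter_maf <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"),
            threshold >= 0, threshold <= 0.5)
  keep <- which(snp_maf(geno) >= threshold)
  if (!length(keep)) warning("no SNPs pass the MAF filter")
  genotype_matrix(geno$codes[, keep, drop = FALSE],
                  geno$map[keep, , drop = FALSE], geno$ids)
}

#' Read genotypes from PLINK or TSV files
#'
#' @param prefix path prefix; files `<prefix>.ped`/`.map`,
#'   `<prefix>.bed`/`.bim`/`.fam` or `<prefix>.geno.tsv`/`.map.tsv` are
#'   read depending on `format`.
#' @param format `"ped_map"` (PLINK text), `"bed_bim_fam"` (PLINK-1 binary,
#'   SNP-major) or `"tsv"` (code matrix with header `id` + SNP ids, plus a
#'   map TSV).
#' @return A `genotype_matrix`; column order follows the file order.
#' @export
read_genotypes <- function(prefix,
                           format = c("ped_map", "bed_bim_fam", "tsv")) {
  format <- match.arg(format)
  switch(format,
         ped_map = read_ped_map(prefix),
         bed_bim_fam = read_bed(prefix),
         tsv = read_geno_tsv(prefix))
}

#' Write genotypes to PLINK or TSV files
#'
#' @param geno a `genotype_matrix`.
#' @inheritParams read_genotypes
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(geno, prefix,
                            format = c("ped_map", "bed_bim_fam", "tsv")) {
  format <- match.arg(format)
  switch(format,
         ped_map = write_ped_map(geno, prefix),
         bed_bim_fam = write_bed(geno, prefix),
         tsv = write_geno_tsv(geno, prefix))
  invisible(prefix)
}

read_ped_map <- function(prefix) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  stopifnot(file.exists(mapf), file.exists(pedf))
  map <- utils::read.table(mapf, header = FALSE, colClasses = "character")
  names(map) <- c("chr", "snp_id", "cm", "pos")[seq_len(ncol(map))]
  map$pos <- as.integer(map$pos)
  ped <- utils::read.table(pedf, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("dimension mismatch: ", m, " SNPs in .map but ",
         ncol(ped) - 6, " allele columns in .ped")
  ids <- ped[[2]]
  codes <- matrix(NA_integer_, nrow(ped), m)
  allele1 <- allele2 <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    a <- ped[[6 + 2 * j - 1]]; b <- ped[[6 + 2 * j]]
    miss <- a == "0" | b == "0"
    if (any(a == "0" & b != "0") || any(b == "0" & a != "0"))
      stop("half-missing genotype at SNP ", map$snp_id[j])
    obs <- sort(unique(c(a[!miss], b[!miss])))
    if (length(obs) > 2)
      stop("more than two alleles at SNP ", map$snp_id[j], ": ",
           paste(obs, collapse = ", "))
    if (length(obs)) {
      allele1[j] <- obs[1]
      allele2[j] <- if (length(obs) == 2) obs[2] else NA_character_
      codes[, j] <- ifelse(miss, NA_integer_,
                           (a == allele2[j]) + (b == allele2[j]))
      codes[is.na(codes[, j]) & !miss, j] <- 0L   # monomorphic
    }
  }
  map2 <- data.frame(snp_id = map$snp_id, chr = map$chr, pos = map$pos,
                     allele1 = allele1, allele2 = allele2,
                     stringsAsFactors = FALSE)
  genotype_matrix(codes, map2, ids)
}

write_ped_map <- function(geno, prefix) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos),
    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  m <- nrow(map)
  al1 <- ifelse(is.na(map$allele1), "1", map$allele1)
  al2 <- ifelse(is.na(map$allele2), "2", map$allele2)
  cols <- vector("list", 2 * m)
  for (j in seq_len(m)) {
    x <- geno$codes[, j]
    cols[[2 * j - 1]] <- ifelse(is.na(x), "0", ifelse(x >= 1, al2[j], al1[j]))
    cols[[2 * j]] <- ifelse(is.na(x), "0", ifelse(x == 2, al2[j], al1[j]))
  }
  ped <- cbind(geno$ids, geno$ids, "0", "0", "0", "-9",
               do.call(cbind, cols))
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     sep = " ", row.names = FALSE, col.names = FALSE)
}

# PLINK-1 .bed: magic 0x6c 0x1b, mode 0x01 (SNP-major); two bits per
# genotype packed from the low bits of each byte:
# 00 = hom allele1, 01 = missing, 10 = het, 11 = hom allele2
read_bed <- function(prefix) {
  bimf <- paste0(prefix, ".bim"); famf <- paste0(prefix, ".fam")
  bedf <- paste0(prefix, ".bed")
  stopifnot(file.exists(bimf), file.exists(famf), file.exists(bedf))
  bim <- utils::read.table(bimf, header = FALSE, colClasses = "character")
  fam <- utils::read.table(famf, header = FALSE, colClasses = "character")
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK-1 .bed file: ", bedf)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpl <- ceiling(n / 4)
  if (length(raw) != 3 + bpl * m)
    stop("dimension mismatch: .bed payload does not match .bim/.fam sizes")
  body <- as.integer(raw[-(1:3)])
  dim(body) <- c(bpl, m)
  codes <- matrix(NA_integer_, n, m)
  lut <- c(0L, NA_integer_, 1L, 2L)   # bit pairs 00,01,10,11
  shifts <- c(0L, 2L, 4L, 6L)
  for (k in 1:4) {
    if (k > n) next
    idx <- seq(k, n, by = 4)
    byte_rows <- ceiling(idx / 4)
    bits <- bitwAnd(bitwShiftR(body[byte_rows, , drop = FALSE],
                               shifts[k]), 3L)
    codes[idx, ] <- lut[bits + 1L]
  }
  map <- data.frame(snp_id = bim[[2]], chr = bim[[1]],
                    pos = as.integer(bim[[4]]),
                    allele1 = bim[[5]], allele2 = bim[[6]],
                    stringsAsFactors = FALSE)
  genotype_matrix(codes, map, fam[[2]])
}

write_bed <- function(geno, prefix) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, map$pos,
               ifelse(is.na(map$allele1), "1", map$allele1),
               ifelse(is.na(map$allele2), "2", map$allele2)),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$ids, geno$ids, "0", "0", "0", "-9"),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  n <- length(geno$ids); m <- nrow(map)
  bpl <- ceiling(n / 4)
  enc <- c(0L, 2L, 3L)   # code 0,1,2 -> bit pairs 00,10,11 (01 = missing)
  body <- matrix(0L, bpl, m)
  for (k in 1:4) {
    if (k > n) next
    idx <- seq(k, n, by = 4)
    x <- geno$codes[idx, , drop = FALSE]
    bits <- matrix(1L, length(idx), m)
    bits[!is.na(x)] <- enc[x[!is.na(x)] + 1L]
    byte_rows <- ceiling(idx / 4)   # distinct within this within-byte slot
    body[byte_rows, ] <- body[byte_rows, , drop = FALSE] +
      bitwShiftL(bits, 2L * (k - 1L))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(body), con)
}

read_geno_tsv <- function(prefix) {
  gf <- paste0(prefix, ".geno.tsv"); mf <- paste0(prefix, ".map.tsv")
  stopifnot(file.exists(gf), file.exists(mf))
  g <- utils::read.table(gf, header = TRUE, sep = "\t", na.strings = ".",
                         check.names = FALSE, colClasses = "character")
  map <- utils::read.table(mf, header = TRUE, sep = "\t", na.strings = ".",
                           stringsAsFactors = FALSE)
  codes <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  if (!identical(colnames(codes), map$snp_id))
    stop("map/genotype SNP mismatch in TSV input")
  genotype_matrix(codes, map, g[[1]])
}

write_geno_tsv <- function(geno, prefix) {
  g <- data.frame(id = geno$ids, geno$codes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(g, paste0(prefix, ".geno.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE, na = ".")
  utils::write.table(geno$map, paste0(prefix, ".map.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE, na = ".")
}

#' Read a phenotype table
#'
#' Tab-separated with header columns `id`, `y`, `pta`; the corrected
#' phenotype `y_star = y - 2 pta` is derived on read.
#' @param path file path.
#' @return Data frame `id`, `y`, `pta`, `y_star`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "y", "pta") %in% names(ph)))
  ph$id <- as.character(ph$id)
  correct_phenotypes(ph)
}

#' Write a phenotype table
#' @param pheno data frame with `id`, `y`, `pta`.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("id", "y", "pta")], path, quote = FALSE,
                     sep = "\t", row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a pedigree
#'
#' Comma-separated with header `animal,sire,dam`; `"0"` = unknown parent.
#' @param path file path.
#' @return Data frame with character columns `animal`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  pedigree_order(ped)   # validates acyclicity
  ped
}

#' Write a pedigree
#' @param ped data frame `animal`, `sire`, `dam`.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("animal", "sire", "dam")], path,
                   quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an effect table as TSV
#'
#' Tab-separated, UTF-8, `"."` for missing values; list columns (epistasis
#' component grids) are dropped. Reading the result back with
#' [read_effect_table()] restores the flat columns exactly.
#' @param records an effect table from a scan or [top_effects()].
#' @param path file path.
#' @export
write_effect_table <- function(records, path) {
  flat <- records[, !vapply(records, is.list, TRUE), drop = FALSE]
  utils::write.table(flat, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read an effect table written by [write_effect_table()]
#' @param path file path.
#' @return Data frame.
#' @export
read_effect_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}
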