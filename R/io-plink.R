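#' Read genotypes from PLINK files
#'
#' Reads a dataset from the binary BED/BIM/FAM trio or the text PED/MAP
#' pair.  \code{path} is the file-set prefix without extension.  Dosages are
#' counted toward allele 1 as declared in the BIM file; in the PED dialect,
#' which does not declare allele order, allele 1 is inferred from the order
#' of alleles within observed heterozygotes, falling back to lexicographic
#' order for SNPs with no heterozygote (see Details).
#'
#' @details The BED reader requires the v1 magic bytes \code{0x6C 0x1B} and
#' the SNP-major mode byte \code{0x01}.  The two-bit genotype codes are
#' decoded as 00 = two copies of allele 1, 10 = heterozygote, 11 = zero
#' copies, 01 = missing.  In PED files the missing genotype is \code{0 0};
#' a half-missing call is treated as missing with a warning.  A PED column
#' in which only one allele is ever observed cannot declare its allele
#' order; it reads back as homozygous for allele 1, so dosages of such
#' SNPs are preserved only up to allele relabeling.  The FAM/PED
#' family id column carries the population label; subgroup and region are
#' not representable in PLINK formats and default to the population.
#'
#' @param path file prefix; \code{path.bed/.bim/.fam} or
#'   \code{path.ped/.map} must exist.
#' @param dialect \code{"bed"} or \code{"ped"}.
#' @return a \code{\link{genotype_dataset}}.
#' @seealso \code{\link{write_genotypes}}
#' @export
read_genotypes <- function(path, dialect = c("bed", "ped")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") read_bed(path) else read_ped(path)
}

#' Write genotypes to PLINK files
#'
#' Inverse of \code{\link{read_genotypes}}: emits BED/BIM/FAM or PED/MAP
#' files such that reading them back reproduces the sample ids, population
#' labels, SNP map and genotype matrix.
#'
#' @param ds a \code{genotype_dataset}; must contain at least one sample
#'   and one SNP.
#' @param path output file prefix.
#' @param dialect \code{"bed"} or \code{"ped"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(ds, path, dialect = c("bed", "ped")) {
  dialect <- match.arg(dialect)
  validate_genotype_dataset(ds)
  if (nrow(ds$genotypes) == 0L || ncol(ds$genotypes) == 0L)
    stop("refusing to write an empty dataset (0 samples or 0 SNPs)")
  if (dialect == "bed") write_bed(ds, path) else write_ped(ds, path)
  invisible(path)
}

## ---- BED/BIM/FAM -----------------------------------------------------------

read_bed <- function(path) {
  bedf <- paste0(path, ".bed")
  bimf <- paste0(path, ".bim")
  famf <- paste0(path, ".fam")
  for (f in c(bedf, bimf, famf))
    if (!file.exists(f)) stop("file not found: ", f)

  bim <- utils::read.table(bimf, header = FALSE, colClasses = "character")
  if (ncol(bim) != 6) stop("BIM file must have 6 columns, found ", ncol(bim))
  snps <- data.frame(chrom = normalize_chrom(bim[[1]]), snp_id = bim[[2]],
                     genetic_pos = as.numeric(bim[[3]]),
                     phys_pos = as.integer(bim[[4]]),
                     allele1 = bim[[5]], allele2 = bim[[6]],
                     stringsAsFactors = FALSE)
  fam <- utils::read.table(famf, header = FALSE, colClasses = "character")
  samples <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                        stringsAsFactors = FALSE)

  n <- nrow(samples)
  m <- nrow(snps)
  bpv <- ceiling(n / 4)   # bytes per variant, SNP-major
  raw <- readBin(bedf, what = "raw", n = 3 + bpv * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a BED v1 file (bad magic bytes) in ", bedf)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files (mode byte 0x01) are supported")
  body <- raw[-(1:3)]
  if (length(body) < bpv * m)
    stop("truncated BED genotype block in ", bedf, ": expected ",
         bpv * m, " bytes, found ", length(body))

  # 256 x 4 lookup: byte value -> allele-1 dosage of its four 2-bit fields,
  # first sample in the low-order bits.
  lut <- bed_decode_table()
  codes <- lut[as.integer(body) + 1L, , drop = FALSE]  # (bpv*m) x 4
  g <- matrix(t(codes), nrow = 4L * bpv)               # per-SNP columns
  g <- g[seq_len(n), , drop = FALSE]
  storage.mode(g) <- "integer"
  genotype_dataset(g, samples, snps)
}

bed_decode_table <- function() {
  two_bit <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  b <- 0:255
  cbind(two_bit[b %% 4 + 1],
        two_bit[(b %/% 4) %% 4 + 1],
        two_bit[(b %/% 16) %% 4 + 1],
        two_bit[(b %/% 64) %% 4 + 1])
}

write_bed <- function(ds, path) {
  n <- nrow(ds$genotypes)
  m <- ncol(ds$genotypes)
  bpv <- ceiling(n / 4)

  g <- ds$genotypes
  v <- matrix(3L, nrow = 4L * bpv, ncol = m)      # pad = code 11 (dosage 0)
  code <- matrix(NA_integer_, n, m)
  code[] <- c(3L, 2L, 0L)[g + 1L]                 # dosage 0,1,2 -> 11,10,00
  code[is.na(g)] <- 1L                            # missing -> 01
  v[seq_len(n), ] <- code
  byte <- v[seq(1, 4 * bpv, by = 4), , drop = FALSE] +
    4L * v[seq(2, 4 * bpv, by = 4), , drop = FALSE] +
    16L * v[seq(3, 4 * bpv, by = 4), , drop = FALSE] +
    64L * v[seq(4, 4 * bpv, by = 4), , drop = FALSE]

  con <- file(paste0(path, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(byte), con)

  write_bim(ds, paste0(path, ".bim"))
  write_fam(ds, paste0(path, ".fam"))
}

write_bim <- function(ds, file) {
  utils::write.table(
    data.frame(ds$snps$chrom, ds$snps$snp_id,
               format(ds$snps$genetic_pos, trim = TRUE, scientific = FALSE),
               ds$snps$phys_pos, ds$snps$allele1, ds$snps$allele2),
    file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
}

write_fam <- function(ds, file) {
  utils::write.table(
    data.frame(ds$samples$population, ds$samples$sample_id, 0, 0, 0, -9),
    file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
}

## ---- PED/MAP ---------------------------------------------------------------

read_ped <- function(path) {
  pedf <- paste0(path, ".ped")
  mapf <- paste0(path, ".map")
  for (f in c(pedf, mapf))
    if (!file.exists(f)) stop("file not found: ", f)

  mp <- utils::read.table(mapf, header = FALSE, colClasses = "character")
  if (ncol(mp) != 4) stop("MAP file must have 4 columns, found ", ncol(mp))
  m <- nrow(mp)

  lines <- readLines(pedf)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  if (n == 0) stop("empty PED file: ", pedf)
  len <- lengths(toks)
  if (any(len != 6 + 2 * m))
    stop("PED line with ", len[which(len != 6 + 2 * m)[1]],
         " fields; expected ", 6 + 2 * m)

  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = tok[, 2], population = tok[, 1],
                        stringsAsFactors = FALSE)
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]   # n x m first alleles
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warning(sum(half), " half-missing PED genotype(s) treated as missing")
    a1[half] <- "0"
    a2[half] <- "0"
  }

  g <- matrix(NA_integer_, n, m)
  allele1 <- character(m)
  allele2 <- character(m)
  for (j in seq_len(m)) {
    obs1 <- a1[, j]
    obs2 <- a2[, j]
    seen <- setdiff(sort(unique(c(obs1, obs2))), "0")
    if (length(seen) > 2)
      stop("SNP ", mp[[2]][j], " has >2 alleles in PED: ",
           paste(seen, collapse = ","))
    het <- which(obs1 != obs2 & obs1 != "0" & obs2 != "0")
    if (length(het)) {
      # our writer emits heterozygotes as "allele1 allele2"
      al1 <- obs1[het[1]]
      al2 <- obs2[het[1]]
    } else if (length(seen) >= 1) {
      al1 <- seen[1]
      al2 <- if (length(seen) == 2) seen[2] else "0"
    } else {
      al1 <- "0"
      al2 <- "0"
    }
    allele1[j] <- al1
    allele2[j] <- al2
    nonmiss <- obs1 != "0"
    g[nonmiss, j] <- (obs1[nonmiss] == al1) + (obs2[nonmiss] == al1)
  }

  snps <- data.frame(chrom = normalize_chrom(mp[[1]]), snp_id = mp[[2]],
                     genetic_pos = as.numeric(mp[[3]]),
                     phys_pos = as.integer(mp[[4]]),
                     allele1 = allele1, allele2 = allele2,
                     stringsAsFactors = FALSE)
  genotype_dataset(g, samples, snps)
}

write_ped <- function(ds, path) {
  g <- ds$genotypes
  n <- nrow(g)
  m <- ncol(g)
  al1 <- ds$snps$allele1
  al2 <- ds$snps$allele2

  first <- matrix(al1[col(g)], n, m)   # dosage 2 and 1 carry allele1 first
  second <- matrix(al2[col(g)], n, m)
  first[!is.na(g) & g == 0] <- second[!is.na(g) & g == 0]
  second[!is.na(g) & g == 2] <- first[!is.na(g) & g == 2]
  first[is.na(g)] <- "0"
  second[is.na(g)] <- "0"

  geno <- matrix("", n, 2 * m)
  geno[, 2 * seq_len(m) - 1] <- first
  geno[, 2 * seq_len(m)] <- second
  out <- cbind(ds$samples$population, ds$samples$sample_id,
               "0", "0", "0", "-9", geno)
  writeLines(apply(out, 1, paste, collapse = " "), paste0(path, ".ped"))

  utils::write.table(
    data.frame(ds$snps$chrom, ds$snps$snp_id,
               format(ds$snps$genetic_pos, trim = TRUE, scientific = FALSE),
               ds$snps$phys_pos),
    paste0(path, ".map"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
}
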