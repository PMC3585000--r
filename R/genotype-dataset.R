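#' Construct a genotype dataset
#'
#' The central data container of the package: an N x M matrix of diploid
#' allele-1 dosages (0, 1, 2, or \code{NA} for missing) together with a
#' sample table and a SNP map.  All pipeline stages consume and return this
#' class.
#'
#' @param genotypes integer or numeric matrix, samples in rows, SNPs in
#'   columns; entries must be 0, 1, 2 or \code{NA}.
#' @param samples data frame with columns \code{sample_id} (unique) and
#'   \code{population}; optional columns \code{subgroup} (defaults to
#'   \code{population}) and \code{region}.
#' @param snps data frame with columns \code{chrom}, \code{snp_id},
#'   \code{genetic_pos} (centiMorgans), \code{phys_pos} (1-based base
#'   pairs), \code{allele1}, \code{allele2}.  Within each chromosome
#'   physical positions must be strictly increasing and genetic positions
#'   non-decreasing, in map order.
#'
#' @return An object of class \code{genotype_dataset}: a list with elements
#'   \code{genotypes}, \code{samples}, \code{snps}.
#' @export
genotype_dataset <- function(genotypes, samples, snps) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)

  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("'samples' needs columns sample_id and population")
  if (is.null(samples$subgroup)) samples$subgroup <- samples$population
  if (is.null(samples$region)) samples$region <- NA_character_
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  samples$subgroup <- as.character(samples$subgroup)

  need <- c("chrom", "snp_id", "genetic_pos", "phys_pos", "allele1", "allele2")
  if (!all(need %in% names(snps)))
    stop("'snps' needs columns ", paste(need, collapse = ", "))
  snps$chrom <- normalize_chrom(snps$chrom)
  snps$snp_id <- as.character(snps$snp_id)
  snps$allele1 <- as.character(snps$allele1)
  snps$allele2 <- as.character(snps$allele2)

  ds <- structure(list(genotypes = genotypes, samples = samples, snps = snps),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  rownames(ds$genotypes) <- samples$sample_id
  colnames(ds$genotypes) <- snps$snp_id
  ds
}

#' Validate a genotype dataset
#'
#' Checks the class invariants: matrix dimensions match the sample and SNP
#' tables, every non-missing dosage is 0/1/2, sample ids are unique, and the
#' SNP map is properly ordered within chromosomes.
#'
#' @param ds a \code{genotype_dataset}.
#' @return \code{ds}, invisibly; errors if an invariant is violated.
#' @export
validate_genotype_dataset <- function(ds) {
  g <- ds$genotypes
  if (nrow(g) != nrow(ds$samples))
    stop("genotype rows (", nrow(g), ") != number of samples (",
         nrow(ds$samples), ")")
  if (ncol(g) != nrow(ds$snps))
    stop("genotype columns (", ncol(g), ") != number of SNPs (",
         nrow(ds$snps), ")")
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad))
    stop("genotype entries must be 0, 1, 2 or NA; found ",
         paste(unique(g[bad]), collapse = ", "))
  if (anyDuplicated(ds$samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(ds$samples$sample_id[duplicated(ds$samples$sample_id)]),
               collapse = ", "))
  for (ch in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == ch)
    pp <- ds$snps$phys_pos[idx]
    gp <- ds$snps$genetic_pos[idx]
    if (any(diff(pp) <= 0))
      stop("phys_pos not strictly increasing on chromosome ", ch)
    if (any(diff(gp) < 0))
      stop("genetic_pos decreasing on chromosome ", ch)
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = " "), "\n")
  cat("  populations:",
      paste(names(table(x$samples$population)), "(",
            as.integer(table(x$samples$population)), ")",
            sep = "", collapse = " "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param ds a \code{genotype_dataset}.
#' @param samples integer or logical index into the sample table.
#' @param snps integer or logical index into the SNP table.
#' @return the subsetted \code{genotype_dataset}.
#' @export
subset_genotypes <- function(ds, samples = NULL, snps = NULL) {
  g <- ds$genotypes
  st <- ds$samples
  mt <- ds$snps
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    st <- st[samples, , drop = FALSE]
    rownames(st) <- NULL
  }
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
    mt <- mt[snps, , drop = FALSE]
    rownames(mt) <- NULL
  }
  structure(list(genotypes = g, samples = st, snps = mt),
            class = "genotype_dataset")
}

# Chromosome labels normalized to character; PLINK numeric codes for the
# sex chromosomes and mitochondrion mapped to their letter names.
normalize_chrom <- function(x) {
  x <- as.character(x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "25"] <- "XY"
  x[x == "26"] <- "MT"
  x[x == "M"] <- "MT"
  x
}

autosome_labels <- function() as.character(1:22)
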