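# Builders for small in-memory datasets used across the test files.

# Random polymorphic dataset on a simple multi-chromosome map.
random_dataset <- function(n = 8, m = 20, seed = 1, miss_rate = 0.05,
                           n_chrom = 2) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss_rate > 0)
    g[sample(length(g), round(miss_rate * length(g)))] <- NA
  per <- ceiling(m / n_chrom)
  chrom <- as.character(rep(seq_len(n_chrom), each = per)[seq_len(m)])
  pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  genotype_dataset(
    g,
    data.frame(sample_id = sprintf("s%02d", 1:n),
               population = rep(c("A", "B"), length.out = n)),
    data.frame(chrom = chrom, snp_id = paste0("snp", 1:m),
               genetic_pos = pos / 1e4, phys_pos = pos,
               allele1 = "A", allele2 = "C"))
}

# Dataset with explicit genotype matrix on a single chromosome.
matrix_dataset <- function(g, gpos = NULL, chrom = "1") {
  g <- as.matrix(g)
  n <- nrow(g); m <- ncol(g)
  if (is.null(gpos)) gpos <- seq_len(m)
  genotype_dataset(
    g,
    data.frame(sample_id = sprintf("s%02d", 1:n), population = "P"),
    data.frame(chrom = rep(chrom, m), snp_id = paste0("snp", 1:m),
               genetic_pos = gpos, phys_pos = seq_len(m) * 100L,
               allele1 = "A", allele2 = "C"))
}

# Two Balding-Nichols populations stacked into one dataset, labels kept.
two_pop_dataset <- function(F = 0.1, n_per = 50, m = 1000, seed = 1) {
  fr <- simulate_ancestral_freqs(m, c(F, F), seed = seed)
  p1 <- simulate_panel(fr[1, ], n_per, seed = seed + 1, population = "pop1")
  p2 <- simulate_panel(fr[2, ], n_per, seed = seed + 2, population = "pop2")
  genotype_dataset(rbind(p1$genotypes, p2$genotypes),
                   rbind(p1$samples, p2$samples), p1$snps)
}

# Least-squares Procrustes residual after translation/rotation/reflection
# (scale fixed), used as an independent oracle for embeddings.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Xc %*% R - Yc)^2))
}
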