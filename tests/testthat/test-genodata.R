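test_that("constructor enforces the dataset invariants", {
  expect_error(matrix_dataset(matrix(3, 2, 2)), "0, 1, 2 or NA")
  expect_error(genotype_dataset(
    matrix(0L, 2, 1),
    data.frame(sample_id = c("a", "a"), population = "P"),
    data.frame(chrom = "1", snp_id = "s1", genetic_pos = 0, phys_pos = 1,
               allele1 = "A", allele2 = "C")), "duplicate sample_id")
  expect_error(genotype_dataset(
    matrix(0L, 1, 2),
    data.frame(sample_id = "a", population = "P"),
    data.frame(chrom = "1", snp_id = c("s1", "s2"), genetic_pos = c(0, 0),
               phys_pos = c(5, 2), allele1 = "A", allele2 = "C")),
    "strictly increasing")
})

test_that("BED genotype bytes follow the published 2-bit layout", {
  ds <- matrix_dataset(matrix(c(2L, 1L, 0L, NA), 4, 1))
  pre <- withr::local_tempfile()
  write_genotypes(ds, pre, "bed")
  raw <- readBin(paste0(pre, ".bed"), "raw", 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  # dosages (2,1,0,missing) -> 2-bit codes (00,10,11,01), first sample in
  # the low bits: 0 + 4*2 + 16*3 + 64*1 = 120
  expect_identical(raw[4], as.raw(120))
  expect_identical(length(raw), 4L)

  back <- read_genotypes(pre, "bed")
  expect_equal(unname(back$genotypes[, 1]), c(2L, 1L, 0L, NA))
})

test_that("BED and PED round trips preserve samples, map and genotypes", {
  for (seed in 1:4) {
    ds <- random_dataset(n = 7, m = 15, seed = seed, miss_rate = 0.1)
    # give every SNP an observed heterozygote: the PED dialect encodes
    # allele order only through heterozygote ordering
    for (j in which(colSums(ds$genotypes == 1, na.rm = TRUE) == 0))
      ds$genotypes[1, j] <- 1L
    for (dialect in c("bed", "ped")) {
      pre <- withr::local_tempfile()
      write_genotypes(ds, pre, dialect)
      back <- read_genotypes(pre, dialect)
      expect_equal(unname(back$genotypes), unname(ds$genotypes))
      expect_equal(back$samples$sample_id, ds$samples$sample_id)
      expect_equal(back$samples$population, ds$samples$population)
      expect_equal(back$snps[c("chrom", "snp_id", "genetic_pos", "phys_pos")],
                   ds$snps[c("chrom", "snp_id", "genetic_pos", "phys_pos")])
    }
    # cross-dialect: BED -> PED -> BED keeps the genotype matrix
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    write_genotypes(ds, p1, "bed")
    mid <- read_genotypes(p1, "bed")
    write_genotypes(mid, p2, "ped")
    final <- read_genotypes(p2, "ped")
    expect_equal(unname(final$genotypes), unname(ds$genotypes))
  }
})

test_that("malformed PLINK input is rejected with informative errors", {
  ds <- random_dataset(n = 4, m = 6, seed = 2, miss_rate = 0)
  pre <- withr::local_tempfile()
  write_genotypes(ds, pre, "bed")

  bad <- withr::local_tempfile()
  raw <- readBin(paste0(pre, ".bed"), "raw", file.size(paste0(pre, ".bed")))
  writeBin(c(as.raw(c(0x00, 0x00)), raw[-(1:2)]), paste0(bad, ".bed"))
  file.copy(paste0(pre, ".bim"), paste0(bad, ".bim"))
  file.copy(paste0(pre, ".fam"), paste0(bad, ".fam"))
  expect_error(read_genotypes(bad, "bed"), "magic")

  trunc <- withr::local_tempfile()
  writeBin(raw[1:(length(raw) - 2)], paste0(trunc, ".bed"))
  file.copy(paste0(pre, ".bim"), paste0(trunc, ".bim"))
  file.copy(paste0(pre, ".fam"), paste0(trunc, ".fam"))
  expect_error(read_genotypes(trunc, "bed"), "truncated")

  expect_error(write_genotypes(subset_genotypes(ds, samples = integer(0)),
                               withr::local_tempfile(), "bed"),
               "empty")
})

test_that("PED missing code 0 0 maps to a missing genotype", {
  ds <- matrix_dataset(matrix(c(2L, NA, 1L, 0L), 2, 2))
  pre <- withr::local_tempfile()
  write_genotypes(ds, pre, "ped")
  ped <- readLines(paste0(pre, ".ped"))
  expect_match(ped[2], " 0 0 ")
  back <- read_genotypes(pre, "ped")
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
})

test_that("qc_filter applies the missingness and autosome rules", {
  # 5 autosomal SNPs with missing fractions 0, 0.005, 0.01, 0.02, 1.0
  n <- 200
  g <- matrix(1L, n, 6)
  g[1, 2] <- NA                      # 0.005
  g[1:2, 3] <- NA                    # 0.01 (boundary, retained)
  g[1:4, 4] <- NA                    # 0.02
  g[, 5] <- NA                       # 1.0
  ds <- genotype_dataset(
    g,
    data.frame(sample_id = sprintf("s%03d", 1:n), population = "P"),
    data.frame(chrom = c("1", "1", "2", "2", "3", "X"),
               snp_id = paste0("m", 1:6),
               genetic_pos = rep(1, 6), phys_pos = c(1, 2, 1, 2, 1, 1),
               allele1 = "A", allele2 = "C"))

  out <- qc_filter(ds, max_snp_missing = 0.01)
  expect_equal(out$snps$snp_id, c("m1", "m2", "m3"))
  expect_equal(attr(out, "qc_removed"),
               c(nonautosomal = 1L, missingness = 2L))
  # retained genotype values are untouched
  expect_identical(out$genotypes, ds$genotypes[, 1:3])
  # samples never removed
  expect_equal(nrow(out$genotypes), n)

  keepx <- qc_filter(ds, max_snp_missing = 1, drop_nonautosomal = FALSE)
  expect_true("m6" %in% keepx$snps$snp_id)
})

test_that("ld_prune removes exactly one of an identical pair and keeps uncorrelated SNPs", {
  set.seed(5)
  base <- sample(0:2, 40, replace = TRUE)
  g <- cbind(base, base, sample(0:2, 40, replace = TRUE))
  ds <- matrix_dataset(g)
  out <- ld_prune(ds, r2_max = 0.4, window_snps = 10, step_snps = 2)
  expect_equal(ncol(out$genotypes), 2)
  # the later duplicate is the one removed (tie-break on map order)
  expect_equal(out$snps$snp_id, c("snp1", "snp3"))

  # constructed orthogonal dosage patterns: all pairwise r2 < 0.4
  g2 <- cbind(c(0, 0, 2, 2, 0, 0, 2, 2),
              c(0, 2, 0, 2, 0, 2, 0, 2),
              c(0, 0, 0, 0, 2, 2, 2, 2))
  r2 <- cor(g2)^2
  expect_true(max(r2[upper.tri(r2)]) < 0.4)
  out2 <- ld_prune(matrix_dataset(g2), r2_max = 0.4,
                   window_snps = 3, step_snps = 1)
  expect_equal(ncol(out2$genotypes), 3)
})

test_that("SNPs never sharing a window are not compared", {
  set.seed(6)
  base <- sample(0:2, 30, replace = TRUE)
  m <- 30
  g <- matrix(sample(0:2, 30 * m, replace = TRUE), 30, m)
  g[, 1] <- base
  g[, m] <- base                     # identical but 30 SNPs apart
  # make the middle uncorrelated enough that nothing else is pruned
  ds <- matrix_dataset(g)
  out <- ld_prune(ds, r2_max = 0.999, window_snps = 5, step_snps = 1)
  expect_true(all(c("snp1", paste0("snp", m)) %in% out$snps$snp_id))
})

test_that("pruned output has no over-threshold pair within any window", {
  for (seed in c(3, 9)) {
    ds <- random_dataset(n = 30, m = 120, seed = seed, miss_rate = 0.05,
                         n_chrom = 2)
    # plant some duplicated columns to give the pruner work
    set.seed(seed + 100)
    for (j in sample(2:60, 10)) ds$genotypes[, j] <- ds$genotypes[, j - 1]
    window <- 15; step <- 4; r2max <- 0.4
    out <- ld_prune(ds, r2_max = r2max, window_snps = window,
                    step_snps = step)
    # exhaustive check: replay the same windows over the retained SNPs
    for (ch in unique(ds$snps$chrom)) {
      idx_all <- which(ds$snps$chrom == ch)
      kept <- ds$snps$snp_id[idx_all] %in% out$snps$snp_id
      for (s in seq(1, length(idx_all), by = step)) {
        win <- idx_all[s:min(s + window - 1, length(idx_all))]
        win <- win[kept[match(win, idx_all)]]
        if (length(win) < 2) next
        r2 <- suppressWarnings(
          cor(ds$genotypes[, win], use = "pairwise.complete.obs"))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        expect_lte(max(r2), r2max)
      }
    }
  }
})

test_that("IBS distances match hand counts and a brute-force oracle", {
  # dosages A=(0,2), B=(0,1): shared alleles 2 and 1 -> similarity 0.75
  ds <- matrix_dataset(rbind(c(0, 2), c(0, 1)))
  D <- ibs_distance_matrix(ds)
  expect_equal(D[1, 2], 0.25)

  expect_equal(ibs_distance_matrix(
    matrix_dataset(rbind(c(0, 0), c(2, 2))))[1, 2], 1)
  expect_equal(ibs_distance_matrix(
    matrix_dataset(rbind(c(1, 2, 0), c(1, 2, 0))))[1, 2], 0)

  ds <- random_dataset(n = 9, m = 10, seed = 4, miss_rate = 0.15)
  D <- ibs_distance_matrix(ds)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  g <- ds$genotypes
  for (i in 1:8) for (j in (i + 1):9) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    shared <- 2 - abs(g[i, ok] - g[j, ok])
    expect_equal(D[i, j], 1 - sum(shared) / (2 * sum(ok)))
  }

  g2 <- rbind(c(1L, NA), c(NA, 1L))
  expect_error(ibs_distance_matrix(matrix_dataset(g2)), "no non-missing")
})

test_that("stratified subsampling draws the requested size per group", {
  ds <- two_pop_dataset(F = 0.01, n_per = 40, m = 30, seed = 8)
  ds$samples$population <- rep(c("chr", "dru", "mus"), length.out = 80)
  sub <- stratified_subsample(ds, "population", per_group = 25, seed = 42)
  expect_equal(nrow(sub$genotypes), 75)
  expect_true(all(table(sub$samples$population) == 25))

  again <- stratified_subsample(ds, "population", per_group = 25, seed = 42)
  expect_identical(sub$samples$sample_id, again$samples$sample_id)

  expect_error(stratified_subsample(ds, "population", per_group = 30,
                                    seed = 1), "smaller than per_group")
  ok <- stratified_subsample(ds, "population", per_group = 30, seed = 1,
                             allow_smaller = TRUE)
  expect_equal(nrow(ok$genotypes), sum(pmin(table(ds$samples$population), 30)))
  expect_error(stratified_subsample(ds, "tribe", 5, 1), "unknown group_field")
})
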