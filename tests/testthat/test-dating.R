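test_that("weighted LD bins match an exhaustive-pair oracle", {
  set.seed(31)
  gpos_cm <- c(0.5, 1.8, 3.1, 7.9)               # one chromosome, 4 SNPs
  adm <- matrix_dataset(matrix(sample(0:2, 6 * 4, replace = TRUE), 6, 4),
                        gpos = gpos_cm)
  r1 <- matrix_dataset(matrix(sample(0:2, 5 * 4, replace = TRUE), 5, 4),
                       gpos = gpos_cm)
  r2 <- matrix_dataset(matrix(sample(0:2, 5 * 4, replace = TRUE), 5, 4),
                       gpos = gpos_cm)
  bw <- 0.01
  curve <- weighted_ld_statistic(adm, r1, r2, bin_width = bw, d_max = 0.1,
                                 min_obs = 2)

  # oracle: explicit loop over all same-chromosome pairs
  delta <- colMeans(r1$genotypes) / 2 - colMeans(r2$genotypes) / 2
  nb <- length(curve$bin_centers)
  wz <- w2 <- z2 <- nn <- numeric(nb)
  for (x in 1:3) for (y in (x + 1):4) {
    d <- abs(gpos_cm[x] - gpos_cm[y]) / 100
    if (d <= 0 || d > 0.1) next
    z <- cor(adm$genotypes[, x], adm$genotypes[, y])
    b <- ceiling(d / bw - 1e-12)
    w <- delta[x] * delta[y]
    wz[b] <- wz[b] + w * z
    w2[b] <- w2[b] + w^2
    z2[b] <- z2[b] + z^2
    nn[b] <- nn[b] + 1
  }
  A_ref <- ifelse(nn > 0, wz / sqrt(w2 * z2), NA_real_)
  expect_equal(curve$A, A_ref, tolerance = 1e-12)
  expect_equal(curve$pair_counts, as.integer(nn))

  # swapping the references flips every weight sign but not the statistic
  swapped <- weighted_ld_statistic(adm, r2, r1, bin_width = bw, d_max = 0.1,
                                   min_obs = 2)
  expect_equal(swapped$A, curve$A, tolerance = 1e-12)

  # A is a correlation over pairs
  expect_true(all(abs(curve$A[!is.na(curve$A)]) <= 1 + 1e-12))

  expect_error(weighted_ld_statistic(adm, r1, r1, bin_width = bw),
               "uninformative")
})

test_that("admixture LD decays with distance and vanishes without admixture", {
  map <- simulate_map(4, 1, 600, seed = 41)
  fr <- simulate_ancestral_freqs(nrow(map), c(0.2, 0.2), seed = 42)
  r1 <- simulate_panel(fr[1, ], 80, seed = 43, map = map, population = "r1")
  r2 <- simulate_panel(fr[2, ], 80, seed = 44, map = map, population = "r2")

  adm <- simulate_admixed(fr[1, ], fr[2, ], map, 150, 0.2, 10, seed = 45)
  curve <- weighted_ld_statistic(adm$dataset, r1, r2, bin_width = 0.02,
                                 d_max = 0.30)
  sel <- !is.na(curve$A) & curve$bin_centers >= 0.005
  rho <- cor(curve$bin_centers[sel], curve$A[sel], method = "spearman")
  expect_lt(rho, -0.8)

  # a pure pop-1 cohort (alpha ~ 1) carries no admixture LD signal
  pure <- simulate_panel(fr[1, ], 150, seed = 46, map = map,
                         population = "pure")
  curve0 <- weighted_ld_statistic(pure, r1, r2, bin_width = 0.02,
                                  d_max = 0.30)
  expect_true(all(abs(curve0$A[!is.na(curve0$A)]) < 0.1))
})

test_that("exponential fit recovers noiseless and degenerate curves", {
  bw <- 0.001
  centers <- (seq_len(300) - 0.5) * bw
  curve <- structure(list(bin_centers = centers,
                          A = 0.08 * exp(-30 * centers),
                          pair_counts = rep(100L, 300),
                          bin_width = bw, chromosomes = "1"),
                     class = "ld_decay_curve")
  fit <- fit_exponential_decay(curve)
  expect_equal(fit$rate_per_morgan, 30, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.08, tolerance = 1e-6)
  expect_equal(fit$date_years, 30 * 25, tolerance = 1e-4)

  flat <- curve
  flat$A <- rep(0.05, 300)
  ffit <- fit_exponential_decay(flat, affine = TRUE)
  expect_equal(ffit$rate_per_morgan, 0)
  expect_equal(ffit$offset, 0.05)

  few <- curve
  few$pair_counts[centers > 0.008] <- 0L
  expect_error(fit_exponential_decay(few), "at least 5")
})

test_that("chromosome jackknife gives zero variance on identical blocks", {
  set.seed(51)
  m_per <- 40
  g1 <- matrix(sample(0:2, 30 * m_per, replace = TRUE), 30, m_per)
  gpos <- sort(runif(m_per, 0.1, 20))           # cM
  mk <- function(g, nchrom) {
    genotype_dataset(
      do.call(cbind, rep(list(g), nchrom)),
      data.frame(sample_id = sprintf("s%02d", seq_len(nrow(g))),
                 population = "P"),
      do.call(rbind, lapply(seq_len(nchrom), function(ch)
        data.frame(chrom = as.character(ch),
                   snp_id = sprintf("c%d_s%d", ch, seq_len(m_per)),
                   genetic_pos = gpos, phys_pos = round(gpos * 1e4),
                   allele1 = "A", allele2 = "C"))))
  }
  adm <- mk(g1, 4)
  r1 <- mk(matrix(sample(0:2, 20 * m_per, replace = TRUE), 20, m_per), 4)
  r2 <- mk(matrix(sample(0:2, 20 * m_per, replace = TRUE), 20, m_per), 4)
  fit <- jackknife_date(adm, r1, r2, bin_width = 0.01, d_min = 0.001,
                        min_obs = 2)
  expect_equal(fit$se_rate, 0, tolerance = 1e-8)
  loo <- attr(fit, "jackknife_rates")
  expect_true(all(abs(loo - fit$rate_per_morgan) < 1e-8))

  # fewer than 3 chromosomes is refused
  adm2 <- mk(g1, 2)
  expect_error(jackknife_date(adm2, mk(r1$genotypes[, 1:m_per], 2),
                              mk(r2$genotypes[, 1:m_per], 2),
                              bin_width = 0.01, min_obs = 2),
               "at least 3 chromosomes")
})

test_that("jackknife mean tracks the full estimate on simulated data", {
  map <- simulate_map(6, 1, 500, seed = 61)
  fr <- simulate_ancestral_freqs(nrow(map), c(0.15, 0.15), seed = 62)
  r1 <- simulate_panel(fr[1, ], 80, seed = 63, map = map, population = "r1")
  r2 <- simulate_panel(fr[2, ], 80, seed = 64, map = map, population = "r2")
  adm <- simulate_admixed(fr[1, ], fr[2, ], map, 150, 0.3, 20, seed = 65)
  fit <- jackknife_date(adm$dataset, r1, r2, bin_width = 0.005)
  loo <- attr(fit, "jackknife_rates")
  expect_equal(mean(loo), fit$rate_per_morgan,
               tolerance = 0.1 * fit$rate_per_morgan)
  expect_gt(fit$se_rate, 0)
})

test_that("FST converts to divergence years by both drift formulas", {
  z <- fst_to_divergence_time(0, 5000, 8000)
  expect_equal(c(z$t_years_low, z$t_years_high), c(0, 0))

  est <- fst_to_divergence_time(0.046, 7006, 9505, formula = "linear")
  expect_equal(est$t_years_low, 2 * 7006 * 0.046 * 25, tolerance = 1e-12)
  expect_equal(est$t_years_high, 2 * 9505 * 0.046 * 25, tolerance = 1e-12)
  expect_equal(est$t_years_low, 16113.8, tolerance = 1e-4)
  expect_equal(est$t_years_high, 21861.5, tolerance = 1e-4)

  lg <- fst_to_divergence_time(0.035, 8677, formula = "log")
  expect_equal(lg$t_years_low, 2 * 8677 * -log(0.965) * 25,
               tolerance = 1e-12)
  expect_equal(lg$t_years_low, 15456.7, tolerance = 1e-4)

  # log formula dominates the linear one and both grow with fst and Ne
  for (f in c(0.01, 0.05, 0.2)) {
    lin <- fst_to_divergence_time(f, 7000, formula = "linear")
    lg <- fst_to_divergence_time(f, 7000, formula = "log")
    expect_gt(lg$t_years_low, lin$t_years_low)
  }
  t1 <- fst_to_divergence_time(0.03, 7000, formula = "linear")$t_years_low
  t2 <- fst_to_divergence_time(0.04, 7000, formula = "linear")$t_years_low
  t3 <- fst_to_divergence_time(0.03, 9000, formula = "linear")$t_years_low
  expect_gt(t2, t1)
  expect_gt(t3, t1)

  expect_error(fst_to_divergence_time(1, 7000), "< 1")
  expect_error(fst_to_divergence_time(-0.1, 7000), "non-negative")
})
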