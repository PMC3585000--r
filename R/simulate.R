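#' Simulate a multi-chromosome SNP map
#'
#' Places SNPs uniformly at random along each chromosome and assigns
#' genetic positions at a constant recombination rate of 1 cM/Mb, so a
#' chromosome of L Morgans spans 100 L megabases.  Positions are strictly
#' increasing within a chromosome.
#'
#' @param n_chrom number of chromosomes (labeled "1", "2", ...).
#' @param morgans_per_chrom genetic length of each chromosome, Morgans.
#' @param snps_per_chrom SNPs per chromosome.
#' @param seed integer seed.
#' @return a SNP table (data frame) with columns \code{chrom},
#'   \code{snp_id}, \code{genetic_pos} (cM), \code{phys_pos},
#'   \code{allele1}, \code{allele2}, usable as the \code{snps} slot of a
#'   \code{\link{genotype_dataset}}.
#' @export
simulate_map <- function(n_chrom, morgans_per_chrom, snps_per_chrom, seed = 1) {
  stopifnot(n_chrom >= 1, snps_per_chrom >= 1, morgans_per_chrom > 0)
  len_bp <- round(morgans_per_chrom * 100 * 1e6)   # 1 cM/Mb
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
      pos <- sort(sample.int(len_bp, snps_per_chrom))
      data.frame(chrom = as.character(ch),
                 snp_id = sprintf("c%d_s%d", ch, seq_len(snps_per_chrom)),
                 genetic_pos = pos / 1e6,          # cM at 1 cM/Mb
                 phys_pos = pos,
                 allele1 = "A", allele2 = "B",
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' Draws an ancestral frequency p ~ Uniform(0.05, 0.95) per SNP, then for
#' each population j with drift coefficient F_j draws its frequency from
#' Beta(p (1-F)/F, (1-p)(1-F)/F), the Balding-Nichols distribution whose
#' mean is p and whose variance is F p (1-p).  Two populations each at
#' drift F from the common ancestor have expected pairwise (Hudson) FST of
#' about 2F/(1+F).  F = 0 copies the ancestral frequency exactly.  The
#' truncated ancestral support avoids near-fixed SNPs, which carry little
#' information and destabilize frequency-difference weights.
#'
#' @param M number of SNPs.
#' @param F_by_pop numeric vector of drift coefficients, one per
#'   population, each in [0, 1).
#' @param seed integer seed.
#' @param p_range support of the ancestral frequency.
#' @return a (populations x M) frequency matrix with entries in (0, 1).
#' @export
simulate_ancestral_freqs <- function(M, F_by_pop, seed = 1,
                                     p_range = c(0.05, 0.95)) {
  if (any(F_by_pop < 0 | F_by_pop >= 1)) stop("each F must be in [0, 1)")
  with_seed(seed, {
    p <- stats::runif(M, p_range[1], p_range[2])
    out <- t(vapply(F_by_pop, function(F) {
      if (F == 0) return(p)
      q <- stats::rbeta(M, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      pmin(pmax(q, 1e-6), 1 - 1e-6)
    }, numeric(M)))
    rownames(out) <- paste0("pop", seq_along(F_by_pop))
    out
  })
}

#' Simulate a reference panel from population frequencies
#'
#' Genotypes are Binomial(2, p_m), independent across SNPs and samples
#' (linkage equilibrium within the population).
#'
#' @param freqs numeric vector of allele-1 frequencies, one per SNP.
#' @param N number of samples.
#' @param seed integer seed.
#' @param map optional SNP table (as from \code{\link{simulate_map}});
#'   defaults to a single evenly spaced chromosome.
#' @param population population label for the sample table.
#' @return a \code{\link{genotype_dataset}}.
#' @export
simulate_panel <- function(freqs, N, seed = 1, map = NULL,
                           population = "pop1") {
  stopifnot(N >= 1)
  M <- length(freqs)
  if (is.null(map)) map <- even_map(M)
  stopifnot(nrow(map) == M)
  g <- with_seed(seed, {
    matrix(stats::rbinom(N * M, 2, rep(freqs, each = N)), N, M)
  })
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", population, seq_len(N)),
    population = population, stringsAsFactors = FALSE)
  genotype_dataset(g, samples, map)
}

even_map <- function(M, span_cm = 100) {
  data.frame(chrom = "1", snp_id = paste0("s", seq_len(M)),
             genetic_pos = seq_len(M) * span_cm / M,
             phys_pos = seq_len(M) * round(1e6 * span_cm / M),
             allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
}

#' Simulate an admixed cohort with known admixture time
#'
#' Realizes the instantaneous two-way admixture model that admixture-LD
#' dating assumes.  For each haploid genome and chromosome, ancestry
#' breakpoints are laid down as a Poisson process of rate \code{n_gens}
#' per Morgan (one expected crossover per Morgan per generation, n_gens
#' generations of recombination since the pulse); each segment's ancestry
#' is population 1 with probability \code{alpha} independently; alleles
#' are then drawn Bernoulli from the segment ancestry's frequency.  A
#' genotype is the sum of two independent haplotypes.  The resulting
#' admixture LD between SNPs at genetic distance d Morgans decays in
#' expectation as exp(-n_gens * d).
#'
#' @param freqs_pop1,freqs_pop2 allele-1 frequencies of the two ancestral
#'   populations (one per SNP).
#' @param map SNP table as from \code{\link{simulate_map}}.
#' @param N number of diploid samples.
#' @param alpha proportion of ancestry from population 1, in (0, 1).
#' @param n_gens generations since the admixture pulse (>= 1).
#' @param seed integer seed.
#' @return list with \code{dataset} (a \code{genotype_dataset}) and
#'   \code{truth}, a \code{sim_truth} list recording \code{alpha},
#'   \code{n_gens}, \code{seed}, the realized ancestry-1 fraction, the
#'   mean breakpoint count per haplotype, and a map summary.
#' @export
simulate_admixed <- function(freqs_pop1, freqs_pop2, map, N, alpha, n_gens,
                             seed = 1) {
  stopifnot(alpha > 0, alpha < 1, n_gens >= 1, N >= 1)
  M <- nrow(map)
  stopifnot(length(freqs_pop1) == M, length(freqs_pop2) == M)
  chroms <- unique(map$chrom)
  gpos <- map$genetic_pos / 100                   # Morgans
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_len <- vapply(chrom_idx, function(ix) max(gpos[ix]), numeric(1))
  if (sum(chrom_len) <= 0) stop("degenerate map: zero genetic length")

  res <- with_seed(seed, {
    g <- matrix(0L, N, M)
    anc1_alleles <- 0
    n_break <- 0
    for (i in seq_len(N)) {
      for (h in 1:2) {
        for (c in seq_along(chroms)) {
          ix <- chrom_idx[[c]]
          L <- chrom_len[c]
          nb <- stats::rpois(1, n_gens * L)
          bp <- sort(stats::runif(nb, 0, L))
          n_break <- n_break + nb
          anc <- stats::rbinom(nb + 1, 1, alpha)  # 1 = ancestry from pop 1
          seg <- findInterval(gpos[ix], bp) + 1
          a <- anc[seg]
          p <- ifelse(a == 1, freqs_pop1[ix], freqs_pop2[ix])
          g[i, ix] <- g[i, ix] + stats::rbinom(length(ix), 1, p)
          anc1_alleles <- anc1_alleles + sum(a)
        }
      }
    }
    list(g = g, anc1_fraction = anc1_alleles / (2 * N * M),
         mean_breakpoints = n_break / (2 * N * length(chroms)))
  })

  samples <- data.frame(sample_id = sprintf("adm_%04d", seq_len(N)),
                        population = "admixed", stringsAsFactors = FALSE)
  ds <- genotype_dataset(res$g, samples, map)
  truth <- structure(list(alpha = alpha, n_gens = n_gens, seed = seed,
                          anc1_fraction = res$anc1_fraction,
                          mean_breakpoints_per_chrom = res$mean_breakpoints,
                          n_chrom = length(chroms),
                          morgans_total = sum(chrom_len), n_snps = M),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Expected FST after drift divergence
#'
#' The forward companion of \code{\link{fst_to_divergence_time}}: two
#' populations of constant diploid effective size \code{ne} separated
#' \code{t_gens} generations ago reach FST = 1 - exp(-t / (2 Ne)) under
#' pure drift.  Exact inverse of the \code{"log"} formula.
#'
#' @param t_gens divergence time in generations (>= 0).
#' @param ne diploid effective population size (> 0).
#' @return the expected FST.
#' @export
fst_from_divergence <- function(t_gens, ne) {
  stopifnot(t_gens >= 0)
  if (ne <= 0) stop("ne must be positive")
  -expm1(-t_gens / (2 * ne))
}
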