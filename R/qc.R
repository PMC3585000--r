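#' Quality-control filter on SNPs
#'
#' Retains SNPs whose per-SNP missing fraction does not exceed
#' \code{max_snp_missing} (the default 0.01 corresponds to a 99\% genotyping
#' success rate) and, by default, drops every non-autosomal SNP (sex-linked,
#' pseudo-autosomal and mitochondrial).  Samples are never removed and
#' retained genotype values are never altered.
#'
#' @param ds a \code{genotype_dataset}.
#' @param max_snp_missing maximum tolerated missing fraction per SNP,
#'   inclusive; in [0, 1].
#' @param drop_nonautosomal if \code{TRUE}, keep only chromosomes 1-22.
#' @return the filtered \code{genotype_dataset}, with an attribute
#'   \code{"qc_removed"} giving the number of SNPs removed by each rule
#'   (non-autosomal first, then missingness).
#' @export
qc_filter <- function(ds, max_snp_missing = 0.01, drop_nonautosomal = TRUE) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1)
  validate_genotype_dataset(ds)

  keep_auto <- if (drop_nonautosomal)
    ds$snps$chrom %in% autosome_labels() else rep(TRUE, nrow(ds$snps))
  miss_frac <- colMeans(is.na(ds$genotypes))
  keep_miss <- miss_frac <= max_snp_missing
  keep <- keep_auto & keep_miss

  removed <- c(nonautosomal = sum(!keep_auto),
               missingness = sum(keep_auto & !keep_miss))
  if (!any(keep))
    warning("qc_filter removed every SNP")
  out <- subset_genotypes(ds, snps = keep)
  attr(out, "qc_removed") <- removed
  out
}

#' Sliding-window LD pruning
#'
#' Greedy windowed pruning of SNPs in linkage disequilibrium.  Windows of
#' \code{window_snps} consecutive SNPs (in map order, per chromosome)
#' advance by \code{step_snps}; within each window, while any pair of
#' still-retained SNPs has squared Pearson correlation of dosages above
#' \code{r2_max}, one SNP of the worst pair is removed.  Ties are broken by
#' removing the SNP with higher missingness, then the later one in map
#' order.  Correlations use pairwise-complete observations; monomorphic
#' SNPs have undefined r^2, treated as 0 (never pruned for LD).
#'
#' On exit no retained pair that ever shared a window has r^2 above the
#' threshold.
#'
#' @param ds a \code{genotype_dataset}.
#' @param r2_max squared-correlation threshold; pairs strictly above it are
#'   broken up (default 0.4).
#' @param window_snps window size in SNPs.
#' @param step_snps window step in SNPs; must be smaller than
#'   \code{window_snps}.
#' @return the pruned \code{genotype_dataset}.
#' @export
ld_prune <- function(ds, r2_max = 0.4, window_snps = 50, step_snps = 5) {
  stopifnot(window_snps > step_snps, step_snps >= 1, r2_max >= 0)
  validate_genotype_dataset(ds)

  g <- ds$genotypes
  miss <- colMeans(is.na(g))
  keep <- rep(TRUE, ncol(g))

  for (ch in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == ch)
    if (length(idx) < 2) next
    starts <- seq(1, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        stats::cor(g[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0       # monomorphic or no overlap
      diag(r2) <- 0
      while (TRUE) {
        worst <- max(r2)
        if (worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1, ]
        pair <- sort(hit)           # window-local indices
        # drop the member with more missing data, then the later in map order
        m1 <- miss[win[pair[1]]]
        m2 <- miss[win[pair[2]]]
        drop_local <- if (m1 > m2) pair[1] else pair[2]
        keep[win[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
  }
  subset_genotypes(ds, snps = keep)
}
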