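#' Identity-by-state distance matrix
#'
#' For each pair of samples, similarity is the fraction of alleles shared
#' by state over the SNPs where both genotypes are observed:
#' (number of SNPs sharing both alleles + 0.5 * number sharing one allele)
#' divided by the number of SNPs compared.  Equivalently, with dosages a
#' and b, per-SNP sharing is 1 - |a - b| / 2.  The distance is one minus
#' the similarity.
#'
#' @param ds a \code{genotype_dataset} with at least two samples.
#' @return an N x N symmetric numeric matrix of class \code{ibs_dist} with
#'   zero diagonal, entries in [0, 1], and sample ids as dimnames.
#' @export
ibs_distance_matrix <- function(ds) {
  g <- ds$genotypes
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples for an IBS matrix")
  ids <- ds$samples$sample_id

  if (!anyNA(g)) {
    d <- as.matrix(stats::dist(g, method = "manhattan")) / (2 * ncol(g))
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      ai <- g[i, ]
      for (j in (i + 1):n) {
        ok <- !is.na(ai) & !is.na(g[j, ])
        m <- sum(ok)
        if (m == 0)
          stop("samples ", ids[i], " and ", ids[j],
               " share no non-missing SNPs")
        d[i, j] <- d[j, i] <- sum(abs(ai[ok] - g[j, ok])) / (2 * m)
      }
    }
  }
  dimnames(d) <- list(ids, ids)
  class(d) <- c("ibs_dist", class(d))
  d
}

#' Stratified random subsample
#'
#' Draws exactly \code{per_group} samples from each level of a grouping
#' column, without replacement, to remove sample-size imbalance between
#' groups before structure analysis.  Reproducible given \code{seed}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param group_field name of the grouping column in the sample table
#'   (\code{"population"}, \code{"subgroup"} or \code{"region"}).
#' @param per_group samples to draw per group.
#' @param seed integer seed.
#' @param allow_smaller if \code{TRUE}, groups smaller than
#'   \code{per_group} are kept whole instead of raising an error.
#' @return the subsampled \code{genotype_dataset}, samples in original
#'   order.
#' @export
stratified_subsample <- function(ds, group_field = "population", per_group,
                                 seed, allow_smaller = FALSE) {
  if (!group_field %in% names(ds$samples))
    stop("unknown group_field: ", group_field)
  groups <- ds$samples[[group_field]]
  sizes <- table(groups)
  if (!allow_smaller && any(sizes < per_group))
    stop("group(s) smaller than per_group = ", per_group, ": ",
         paste(names(sizes)[sizes < per_group], collapse = ", "),
         " (use allow_smaller = TRUE to keep them whole)")

  picked <- with_seed(seed, {
    unlist(lapply(unique(groups), function(gr) {
      members <- which(groups == gr)
      k <- min(per_group, length(members))
      sort(members[sample.int(length(members), k)])
    }))
  })
  subset_genotypes(ds, samples = sort(picked))
}
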