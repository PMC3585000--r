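#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in Euclidean space by double-centering the
#' matrix of squared distances, B = -J D^2 J / 2 with J the centering
#' matrix, and taking the top eigenvectors scaled by the square roots of
#' their (non-negative) eigenvalues.  Negative eigenvalues, which arise
#' when the distances are not exactly Euclidean, are truncated to unused.
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. from
#'   \code{\link{ibs_distance_matrix}}); dimnames, if present, are carried
#'   to the result.
#' @param dims number of embedding dimensions requested.  If fewer
#'   positive eigenvalues exist, fewer columns are returned with a
#'   warning.
#' @return an object of class \code{embedding}: list with \code{labels},
#'   \code{coords} (N x k), \code{eigenvalues} (all N, non-increasing) and
#'   \code{method = "mds"}.
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), dims >= 1)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")

  B <- -0.5 * dcenter(D^2)
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
  k <- min(dims, length(pos))
  if (k < dims)
    warning("only ", k, " positive eigenvalue(s); returning ", k,
            " dimension(s)")
  coords <- if (k > 0)
    e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k) else matrix(0, n, 0)
  coords <- fix_signs(coords)
  labels <- if (!is.null(rownames(D))) rownames(D) else as.character(seq_len(n))
  rownames(coords) <- labels
  structure(list(labels = labels, coords = coords,
                 eigenvalues = e$values, method = "mds"),
            class = "embedding")
}

dcenter <- function(M) {
  rm <- rowMeans(M)
  sweep(sweep(M, 1, rm), 2, rm) + mean(M)
}

#' Variance-normalized principal component analysis
#'
#' PCA of the genotype matrix with per-SNP normalization by the binomial
#' standard deviation: each SNP column is centered by its mean dosage and
#' divided by sqrt(p(1-p)) where p = mean dosage / 2, the normalization
#' that weights SNPs by their information about drift.  Missing genotypes
#' are imputed to the column mean (so they contribute nothing after
#' centering); monomorphic columns are dropped.
#'
#' Sample scores are eigenvectors of the sample-by-sample covariance of
#' the normalized matrix, scaled by the square roots of the eigenvalues.
#' Each component is oriented so that its largest-magnitude score is
#' positive, making the output deterministic.
#'
#' @param ds a \code{genotype_dataset} with at least two samples.
#' @param n_pcs number of components to return (at most N - 1).
#' @return an \code{embedding} with \code{method = "pca"}.
#' @export
pca_normalized <- function(ds, n_pcs = 10) {
  g <- ds$genotypes
  n <- nrow(g)
  stopifnot(n >= 2, n_pcs >= 1)
  n_pcs <- min(n_pcs, n - 1)

  X <- normalize_genotypes(g)
  if (ncol(X) == 0) stop("all SNPs are monomorphic; PCA undefined")

  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- n_pcs
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  coords <- fix_signs(coords)
  rownames(coords) <- ds$samples$sample_id
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(labels = ds$samples$sample_id, coords = coords,
                 eigenvalues = ev[seq_len(k)], method = "pca"),
            class = "embedding")
}

# center by mean dosage, scale by sqrt(p(1-p)), mean-impute missing,
# drop monomorphic columns
normalize_genotypes <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  p <- mu / 2
  poly <- is.finite(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  mu <- mu[poly]
  p <- p[poly]
  X <- sweep(g, 2, mu)
  X[is.na(X)] <- 0
  sweep(X, 2, sqrt(p * (1 - p)), "/")
}

# orient each column so its largest-magnitude entry is positive
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding (", x$method, "): ", length(x$labels), " samples x ",
      ncol(x$coords), " dimensions\n", sep = "")
  cat("  top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' Iterative PCA-based outlier removal
#'
#' Extracts the core cluster of a cohort by repeatedly running
#' \code{\link{pca_normalized}} and removing every sample whose score on
#' any of the top \code{n_pcs} components lies more than \code{sigma}
#' standard deviations from that component's mean, until no sample is
#' removed or \code{max_iter} iterations have run.  The defaults (6
#' standard deviations, 10 components, 5 iterations) follow the
#' established smartpca convention.
#'
#' @param ds a \code{genotype_dataset} with more samples than \code{n_pcs}.
#' @param sigma removal threshold in standard deviations.
#' @param n_pcs number of top components scanned.
#' @param max_iter maximum number of remove-and-recompute rounds.
#' @return list with \code{dataset} (the trimmed \code{genotype_dataset})
#'   and \code{report}, a list with \code{removed_ids} (one character
#'   vector per iteration), \code{sigma}, \code{n_pcs} and
#'   \code{iterations}.
#' @export
pca_outlier_removal <- function(ds, sigma = 6, n_pcs = 10, max_iter = 5) {
  stopifnot(nrow(ds$genotypes) > n_pcs, sigma > 0, max_iter >= 1)
  removed <- list()
  current <- ds
  for (it in seq_len(max_iter)) {
    emb <- pca_normalized(current, n_pcs = n_pcs)
    sc <- scale(emb$coords)           # per-PC z-scores
    out <- rowSums(abs(sc) > sigma, na.rm = TRUE) > 0
    if (!any(out)) break
    if (sum(!out) < 3) {
      warning("outlier removal stopped: fewer than 3 samples would remain")
      break
    }
    removed[[length(removed) + 1]] <- current$samples$sample_id[out]
    current <- subset_genotypes(current, samples = !out)
  }
  list(dataset = current,
       report = list(removed_ids = removed, sigma = sigma, n_pcs = n_pcs,
                     iterations = length(removed)))
}
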