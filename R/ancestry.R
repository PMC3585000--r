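#' Binomial admixture log-likelihood
#'
#' Log-likelihood of the standard admixture model: individual i's genotype
#' at SNP m is Binomial(2, pi_im) with pi_im = sum_k Q_ik P_km, where Q
#' holds per-individual ancestry proportions and P per-component allele
#' frequencies.  Returns the sum over non-missing entries of
#' g*log(pi) + (2-g)*log(1-pi); the binomial coefficient, constant in the
#' parameters, is omitted.
#'
#' @param ds a \code{genotype_dataset}.
#' @param Q N x K matrix of ancestry proportions (rows sum to 1).
#' @param P K x M matrix of component allele frequencies.
#' @return the log-likelihood (0 for an all-missing dataset).  A mixture
#'   frequency of exactly 0 or 1 at a non-missing entry whose genotype has
#'   positive probability zero is an error.
#' @export
admixture_loglik <- function(ds, Q, P) {
  g <- ds$genotypes
  Q <- as.matrix(Q)
  P <- as.matrix(P)
  if (nrow(Q) != nrow(g) || ncol(P) != ncol(g) || ncol(Q) != nrow(P))
    stop("Q/P dimensions inconsistent with the dataset")
  pim <- Q %*% P
  obs <- !is.na(g)
  if (!any(obs)) return(0)
  gg <- g[obs]
  pp <- pim[obs]
  bad <- (pp <= 0 & gg > 0) | (pp >= 1 & gg < 2)
  if (any(bad))
    stop("mixture frequency 0 or 1 incompatible with observed genotype at ",
         sum(bad), " entr(ies); log-likelihood is -Inf")
  sum(ifelse(gg > 0, gg * log(pp), 0) +
        ifelse(gg < 2, (2 - gg) * log1p(-pp), 0))
}

#' Fit the admixture model by alternating EM updates
#'
#' Unsupervised maximum-likelihood decomposition of a genotype matrix into
#' K ancestral components under the binomial admixture likelihood (the
#' STRUCTURE/ADMIXTURE model), using the classical EM updates that
#' alternate between the ancestry proportions Q and the component
#' frequencies P.  Each update cannot decrease the likelihood, so the
#' recorded trace is monotone.  Components are relabeled on exit by
#' descending total ancestry mass, which makes output deterministic per
#' seed.
#'
#' Initialization: Q rows drawn from a flat Dirichlet; P from the observed
#' allele frequencies perturbed by seeded noise.  P is kept in
#' [1e-6, 1 - 1e-6] throughout so the likelihood stays finite.
#'
#' @param ds a \code{genotype_dataset} with at least one polymorphic SNP.
#' @param K number of ancestral components (1 <= K <= N).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood gain of an iteration falls
#'   below this.
#' @return an object of class \code{admixture_fit}: list with \code{K},
#'   \code{Q}, \code{P}, \code{loglik_trace}, \code{loglik}, \code{seed},
#'   \code{converged}, \code{n_iter}.
#' @export
fit_admixture <- function(ds, K, seed = 1, max_iter = 500, tol = 1e-4) {
  g <- ds$genotypes
  n <- nrow(g)
  m <- ncol(g)
  stopifnot(K >= 1)
  if (K > n) stop("K = ", K, " exceeds the number of samples (", n, ")")
  freq <- colMeans(g, na.rm = TRUE) / 2
  if (!any(freq > 0 & freq < 1, na.rm = TRUE))
    stop("dataset has no polymorphic SNP")

  obs <- !is.na(g)
  G <- g
  G[!obs] <- 0L
  storage.mode(G) <- "double"
  G2 <- (2 - G) * obs                 # (2 - g) masked to observed entries
  G1 <- G * obs
  msum <- rowSums(obs)                # SNPs observed per sample

  eps <- 1e-6
  init <- with_seed(seed, {
    Q0 <- matrix(stats::rgamma(n * K, 1), n, K)
    Q0 <- Q0 / rowSums(Q0)
    P0 <- matrix(rep(freq, each = K), K, m) +
      matrix(stats::rnorm(K * m, 0, 0.05), K, m)
    list(Q = Q0, P = pmin(pmax(P0, eps), 1 - eps))
  })
  Q <- init$Q
  P <- init$P

  if (K == 1) {
    # closed form: P is the observed allele frequency, Q identically 1
    P <- matrix(pmin(pmax(freq, eps), 1 - eps), 1, m)
    Q <- matrix(1, n, 1)
    ll <- admixture_loglik(ds, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik_trace = ll,
                          loglik = ll, seed = seed, converged = TRUE,
                          n_iter = 0L),
                     class = "admixture_fit"))
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    PI <- Q %*% P
    PI[PI < eps] <- eps
    PI[PI > 1 - eps] <- 1 - eps
    R1 <- G1 / PI                     # g / pi, zero where missing
    R0 <- G2 / (1 - PI)               # (2-g) / (1-pi), zero where missing

    # expected ancestry-allele counts, factored through matrix products
    A <- (R1 %*% t(P)) * Q            # N x K: sum_m a_imk
    B <- (R0 %*% t(1 - P)) * Q        # N x K: sum_m b_imk
    Qnew <- (A + B) / (2 * msum)
    Qnew <- Qnew / rowSums(Qnew)      # guard against masked-entry rounding

    Ca <- t(crossprod(R1, Q)) * P     # K x M: sum_i a_imk
    Cb <- t(crossprod(R0, Q)) * (1 - P)
    Pnew <- Ca / (Ca + Cb)
    Pnew[!is.finite(Pnew)] <- 0.5     # SNP unobserved for a component
    Pnew <- pmin(pmax(Pnew, eps), 1 - eps)

    Q <- Qnew
    P <- Pnew
    # likelihood at the updated parameters, with the same clipping as above
    PI <- Q %*% P
    PI[PI < eps] <- eps
    PI[PI > 1 - eps] <- 1 - eps
    ll <- sum(G1 * log(PI)) + sum(G2 * log1p(-PI))
    if (ll - ll_old < tol && it > 1) {
      converged <- ll - ll_old >= 0 || abs(ll - ll_old) < tol
      if (ll >= ll_old) trace <- c(trace, ll)
      break
    }
    trace <- c(trace, ll)
    ll_old <- ll
  }

  ord <- order(colSums(Q), decreasing = TRUE)
  Q <- Q[, ord, drop = FALSE]
  P <- P[ord, , drop = FALSE]
  rownames(Q) <- ds$samples$sample_id
  colnames(Q) <- paste0("C", seq_len(K))
  rownames(P) <- paste0("C", seq_len(K))
  colnames(P) <- ds$snps$snp_id

  structure(list(K = as.integer(K), Q = Q, P = P, loglik_trace = trace,
                 loglik = trace[length(trace)], seed = seed,
                 converged = converged, n_iter = it),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, "|", nrow(x$Q), "samples,",
      ncol(x$P), "SNPs\n")
  cat(sprintf("  loglik %.2f after %d iteration(s)%s\n", x$loglik, x$n_iter,
              if (x$converged) " (converged)" else ""))
  cat("  component mass:",
      paste(signif(colMeans(x$Q), 3), collapse = " "), "\n")
  invisible(x)
}

#' Cross-validation over the number of ancestral components
#'
#' Estimates out-of-sample predictive error for each candidate K by
#' masking random subsets of genotype entries.  Non-missing entries are
#' partitioned into \code{folds} disjoint masks; for each fold the masked
#' entries are set to missing, the model is refit, and the held-out
#' dosages are predicted as 2 * sum_k Q_ik P_km.  The CV error for K is
#' the mean squared deviation of predictions from held-out genotypes,
#' pooled across folds.
#'
#' @param ds a \code{genotype_dataset}.
#' @param K_list integer vector of K values to evaluate.
#' @param folds number of folds (>= 2).
#' @param seed integer seed controlling both the partition and the fold
#'   refits.
#' @param max_iter EM iteration cap per refit; the default trades a little
#'   convergence for speed, which leaves the ranking of K values intact.
#' @param tol EM stopping tolerance per refit.
#' @return an object of class \code{admixture_cv}: list with \code{K},
#'   \code{cv_error}, \code{folds}, \code{seed}, \code{best_K}.
#' @export
admixture_cv <- function(ds, K_list, folds = 5, seed = 1,
                         max_iter = 100, tol = 1e-3) {
  if (length(K_list) == 0) stop("K_list is empty")
  stopifnot(folds >= 2)
  g <- ds$genotypes
  obs_idx <- which(!is.na(g))
  fold_of <- with_seed(sub_seed(seed, "cv_partition"), {
    sample(rep_len(seq_len(folds), length(obs_idx)))
  })

  err <- sapply(K_list, function(K) {
    se <- 0
    cnt <- 0
    for (f in seq_len(folds)) {
      held <- obs_idx[fold_of == f]
      gm <- g
      gm[held] <- NA_integer_
      dsm <- ds
      dsm$genotypes <- gm
      fit <- fit_admixture(dsm, K, seed = sub_seed(seed, paste0("fold", f)),
                           max_iter = max_iter, tol = tol)
      pred <- 2 * (fit$Q %*% fit$P)
      se <- se + sum((pred[held] - g[held])^2)
      cnt <- cnt + length(held)
    }
    se / cnt
  })

  structure(list(K = as.integer(K_list), cv_error = err,
                 folds = as.integer(folds), seed = seed,
                 best_K = as.integer(K_list[which.min(err)])),
            class = "admixture_cv")
}

#' @export
print.admixture_cv <- function(x, ...) {
  cat("admixture_cv (", x$folds, "folds ):\n")
  print(data.frame(K = x$K, cv_error = signif(x$cv_error, 5)),
        row.names = FALSE)
  cat("  lowest CV error at K =", x$best_K, "\n")
  invisible(x)
}

#' FST between two ancestral components
#'
#' Fixation index between two rows of a component allele-frequency matrix,
#' as a ratio of averages across SNPs (numerator and denominator summed
#' over SNPs before dividing, which weights SNPs consistently).
#' \code{hudson}: sum (p_k - p_l)^2 / sum [p_k(1-p_l) + p_l(1-p_k)].
#' \code{nei}: sum (p_k - p_l)^2 / 2 over sum pbar(1-pbar) with pbar the
#' two-component mean frequency.
#'
#' @param P K x M component frequency matrix (rows in [0, 1]), e.g. from
#'   \code{\link{fit_admixture}}, or any two-row frequency matrix.
#' @param k,l row indices of the two components.
#' @param estimator \code{"hudson"} (default) or \code{"nei"}.
#' @return FST in [0, 1).
#' @export
component_fst <- function(P, k = 1, l = 2, estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  P <- as.matrix(P)
  pk <- as.numeric(P[k, ])
  pl <- as.numeric(P[l, ])
  if (any(pk < 0 | pk > 1 | pl < 0 | pl > 1))
    stop("frequencies must lie in [0, 1]")

  if (estimator == "hudson") {
    num <- sum((pk - pl)^2)
    den <- sum(pk * (1 - pl) + pl * (1 - pk))
  } else {
    pbar <- (pk + pl) / 2
    num <- sum((pk - pl)^2) / 2
    den <- sum(pbar * (1 - pbar))
  }
  if (den == 0)
    stop("FST undefined: both components fixed at every SNP")
  min(max(num / den, 0), 1 - 1e-12)
}
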