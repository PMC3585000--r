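#' Weighted admixture-LD decay curve
#'
#' Computes the admixture-LD statistic used to date admixture events.  Each
#' SNP receives a weight delta_m equal to the allele-frequency difference
#' between the two reference panels.  For every same-chromosome SNP pair
#' (x, y) whose genetic distance d lies in (0, d_max], z(x, y) is the
#' Pearson correlation of dosages at x and y across the admixed samples
#' (pairwise-complete; pairs with fewer than \code{min_obs} complete
#' observations are skipped).  Pairs are binned by d, and per bin
#'
#'   A(d) = sum delta_x delta_y z / sqrt(sum (delta_x delta_y)^2 * sum z^2)
#'
#' the correlation, over the bin's pairs, between the weight product and
#' the observed LD.  Under a single admixture pulse n generations ago,
#' E[A(d)] decays as exp(-n d) in d Morgans, which
#' \code{\link{fit_exponential_decay}} exploits.
#'
#' @param admixed a \code{genotype_dataset} of admixed samples.
#' @param ref1,ref2 \code{genotype_dataset} reference panels for the two
#'   ancestries; all three must share the same SNP map.
#' @param bin_width bin width in Morgans (default 0.001 = 0.1 cM).
#' @param d_max largest genetic distance considered, Morgans.
#' @param min_obs minimum complete observations for a pair's correlation.
#' @return an object of class \code{ld_decay_curve}: list with
#'   \code{bin_centers} (Morgans), \code{A}, \code{pair_counts},
#'   \code{bin_width}, \code{chromosomes}, and per-chromosome bin sums
#'   (used by the jackknife) in \code{chrom_sums}.
#' @export
weighted_ld_statistic <- function(admixed, ref1, ref2, bin_width = 0.001,
                                  d_max = 0.30, min_obs = 10) {
  check_same_map(admixed, ref1, ref2)
  if (nrow(ref1$genotypes) == 0 || nrow(ref2$genotypes) == 0)
    stop("reference panels must be non-empty")

  f1 <- colMeans(ref1$genotypes, na.rm = TRUE) / 2
  f2 <- colMeans(ref2$genotypes, na.rm = TRUE) / 2
  delta <- f1 - f2
  delta[!is.finite(delta)] <- 0
  if (all(delta == 0))
    stop("uninformative references: allele frequencies identical everywhere")

  nbins <- ceiling(d_max / bin_width - 1e-9)
  chroms <- unique(admixed$snps$chrom)
  sums <- lapply(chroms, function(ch) {
    idx <- which(admixed$snps$chrom == ch)
    wld_chrom_sums(admixed$genotypes[, idx, drop = FALSE],
                   delta[idx], admixed$snps$genetic_pos[idx] / 100,
                   bin_width, d_max, nbins, min_obs)
  })
  names(sums) <- chroms
  snp_counts <- vapply(chroms, function(ch) sum(admixed$snps$chrom == ch),
                       integer(1))
  names(snp_counts) <- chroms

  curve_from_sums(sums, snp_counts, bin_width, nbins, chroms)
}

# Per-chromosome accumulation of the bin sums sum(wz), sum(w^2), sum(z^2)
# and pair counts, where w = delta_x * delta_y and z is the dosage
# correlation of the pair.  gpos in Morgans.
wld_chrom_sums <- function(g, delta, gpos, bin_width, d_max, nbins, min_obs) {
  m <- ncol(g)
  zero <- list(wz = numeric(nbins), w2 = numeric(nbins),
               z2 = numeric(nbins), n = integer(nbins))
  if (m < 2) return(zero)

  if (!anyNA(g)) {
    z <- suppressWarnings(stats::cor(g))
    nobs <- matrix(nrow(g), m, m)
  } else {
    z <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    nobs <- crossprod(!is.na(g))
  }
  z[!is.finite(z)] <- NA               # monomorphic columns

  ut <- upper.tri(z)
  d <- abs(outer(gpos, gpos, "-"))[ut]
  zz <- z[ut]
  no <- nobs[ut]
  ww <- tcrossprod(delta)[ut]

  keep <- d > 0 & d <= d_max & !is.na(zz) & no >= min_obs
  if (!any(keep)) return(zero)
  d <- d[keep]
  zz <- zz[keep]
  ww <- ww[keep]
  bin <- pmin(ceiling(d / bin_width - 1e-12), nbins)

  list(wz = bin_accum(ww * zz, bin, nbins),
       w2 = bin_accum(ww^2, bin, nbins),
       z2 = bin_accum(zz^2, bin, nbins),
       n = as.integer(bin_accum(rep(1, length(bin)), bin, nbins)))
}

bin_accum <- function(x, bin, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

curve_from_sums <- function(sums, snp_counts, bin_width, nbins, chroms) {
  wz <- Reduce(`+`, lapply(sums, `[[`, "wz"))
  w2 <- Reduce(`+`, lapply(sums, `[[`, "w2"))
  z2 <- Reduce(`+`, lapply(sums, `[[`, "z2"))
  n <- Reduce(`+`, lapply(sums, `[[`, "n"))
  A <- ifelse(n > 0 & w2 > 0 & z2 > 0, wz / sqrt(w2 * z2), NA_real_)
  structure(list(bin_centers = (seq_len(nbins) - 0.5) * bin_width,
                 A = A, pair_counts = n, bin_width = bin_width,
                 chromosomes = chroms,
                 chrom_sums = sums, snp_counts = snp_counts),
            class = "ld_decay_curve")
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  used <- sum(x$pair_counts > 0)
  cat("ld_decay_curve:", used, "occupied bins of width",
      x$bin_width, "Morgans,", sum(x$pair_counts), "SNP pairs,",
      length(x$chromosomes), "chromosome(s)\n")
  invisible(x)
}

check_same_map <- function(...) {
  dss <- list(...)
  ref <- dss[[1]]$snps
  for (ds in dss[-1]) {
    s <- ds$snps
    if (nrow(s) != nrow(ref) ||
        !all(s$snp_id == ref$snp_id) || !all(s$chrom == ref$chrom) ||
        !all(s$genetic_pos == ref$genetic_pos))
      stop("datasets do not share the same SNP map")
  }
  invisible(TRUE)
}

#' Fit an exponential to an admixture-LD decay curve
#'
#' Weighted nonlinear least squares of A(d) = amplitude * exp(-rate * d),
#' optionally plus a constant offset, over bins with d in
#' [d_min, d_max], each bin weighted by its pair count.  The decay rate in
#' inverse Morgans estimates the number of generations since admixture;
#' the date in years is rate * gen_time.
#'
#' @param curve an \code{ld_decay_curve}.
#' @param d_min,d_max fit window in Morgans (defaults 0.005-0.30, i.e.
#'   0.5-30 cM, excluding the shortest distances where background LD
#'   dominates).
#' @param affine include a constant offset term.
#' @param gen_time generation time in years used to convert the rate to a
#'   date (default 25).
#' @return an object of class \code{decay_fit}: list with
#'   \code{amplitude}, \code{rate_per_morgan}, \code{offset}, \code{rss},
#'   \code{se_rate} (NA until a jackknife is run), \code{gen_time},
#'   \code{date_years}, \code{date_se_years}, \code{n_bins}.
#' @export
fit_exponential_decay <- function(curve, d_min = 0.005, d_max = 0.30,
                                  affine = FALSE, gen_time = 25) {
  sel <- which(curve$bin_centers >= d_min & curve$bin_centers <= d_max &
                 !is.na(curve$A) & curve$pair_counts > 0)
  if (length(sel) < 5)
    stop("need at least 5 non-missing bins in [", d_min, ", ", d_max, "]")
  d <- curve$bin_centers[sel]
  A <- curve$A[sel]
  w <- as.numeric(curve$pair_counts[sel])

  if (diff(range(A)) < 1e-12) {
    # flat curve: no decay; attribute the level to the offset when one is
    # fitted, to the amplitude otherwise
    return(structure(list(amplitude = if (affine) 0 else mean(A),
                          rate_per_morgan = 0,
                          offset = if (affine) mean(A) else 0,
                          rss = 0, se_rate = NA_real_, gen_time = gen_time,
                          date_years = 0, date_se_years = NA_real_,
                          n_bins = length(sel), d_min = d_min, d_max = d_max,
                          affine = affine),
                     class = "decay_fit"))
  }

  fit <- fit_exp_nls(d, A, w, affine)
  if (is.null(fit))
    stop("exponential decay fit failed to converge after restarts; ",
         "bins: ", length(sel), ", A range: ",
         paste(signif(range(A), 3), collapse = " .. "))
  cf <- stats::coef(fit)
  rate <- max(unname(cf["r"]), 0)
  structure(list(amplitude = unname(cf["a"]),
                 rate_per_morgan = rate,
                 offset = if (affine) unname(cf["c"]) else 0,
                 rss = sum(stats::residuals(fit)^2 * w),
                 se_rate = NA_real_,
                 gen_time = gen_time,
                 date_years = rate * gen_time,
                 date_se_years = NA_real_,
                 n_bins = length(sel),
                 d_min = d_min, d_max = d_max, affine = affine),
            class = "decay_fit")
}

# nlsLM with a small grid of starting values; rate bounded below at 0
fit_exp_nls <- function(d, A, w, affine) {
  a0 <- max(A[which.min(d)], 0.01)
  # crude rate guess from a log-linear fit on positive values
  pos <- A > 0
  r0 <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(A[pos]) ~ d[pos]))[2]
    max(-sl, 1)
  } else 10
  starts <- unique(c(r0, 1, 10, 50, 200))

  for (r in starts) {
    fit <- tryCatch({
      if (affine)
        minpack.lm::nlsLM(A ~ a * exp(-r * d) + c,
                          start = list(a = a0, r = r, c = 0),
                          lower = c(a = -Inf, r = 0, c = -Inf),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(A ~ a * exp(-r * d),
                          start = list(a = a0, r = r),
                          lower = c(a = -Inf, r = 0),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: rate %.2f / Morgan (n generations), amplitude %.4g",
              x$rate_per_morgan, x$amplitude))
  if (x$affine) cat(sprintf(", offset %.4g", x$offset))
  cat("\n")
  if (is.na(x$se_rate))
    cat(sprintf("  date: %.0f years (gen_time %g)\n", x$date_years,
                x$gen_time))
  else
    cat(sprintf("  date: %.0f +/- %.0f years (gen_time %g, jackknife)\n",
                x$date_years, x$date_se_years, x$gen_time))
  invisible(x)
}

#' Admixture date with a chromosome-jackknife standard error
#'
#' Computes the weighted-LD decay curve, fits the exponential decay on the
#' full data, then re-fits leaving out one chromosome at a time.  The
#' standard error of the rate comes from the delete-one block jackknife
#' weighted by the number of SNPs per chromosome, and is converted to
#' years with the same generation time.
#'
#' @inheritParams weighted_ld_statistic
#' @inheritParams fit_exponential_decay
#' @return a \code{decay_fit} with \code{se_rate} and
#'   \code{date_se_years} filled in, plus attributes
#'   \code{"jackknife_rates"} (leave-one-chromosome-out rates) and
#'   \code{"curve"} (the full \code{ld_decay_curve}).
#' @export
jackknife_date <- function(admixed, ref1, ref2, bin_width = 0.001,
                           d_max_pairs = 0.30, d_min = 0.005, d_max = 0.30,
                           affine = FALSE, gen_time = 25, min_obs = 10) {
  curve <- weighted_ld_statistic(admixed, ref1, ref2,
                                 bin_width = bin_width, d_max = d_max_pairs,
                                 min_obs = min_obs)
  chroms <- curve$chromosomes
  if (length(chroms) < 3)
    stop("chromosome jackknife needs at least 3 chromosomes, found ",
         length(chroms))

  full <- fit_exponential_decay(curve, d_min = d_min, d_max = d_max,
                                affine = affine, gen_time = gen_time)
  nbins <- length(curve$bin_centers)

  loo <- vapply(seq_along(chroms), function(j) {
    sub <- curve_from_sums(curve$chrom_sums[-j], curve$snp_counts[-j],
                           curve$bin_width, nbins, chroms[-j])
    fit_exponential_decay(sub, d_min = d_min, d_max = d_max,
                          affine = affine, gen_time = gen_time)$rate_per_morgan
  }, numeric(1))

  # weighted delete-one jackknife (block weights = SNPs per chromosome)
  mj <- as.numeric(curve$snp_counts)
  ntot <- sum(mj)
  gch <- length(chroms)
  theta <- full$rate_per_morgan
  hj <- ntot / mj
  theta_J <- gch * theta - sum((1 - mj / ntot) * loo)
  tau <- hj * theta - (hj - 1) * loo
  var_J <- sum((tau - theta_J)^2 / (hj - 1)) / gch
  se <- sqrt(max(var_J, 0))

  full$se_rate <- se
  full$date_se_years <- se * gen_time
  attr(full, "jackknife_rates") <- stats::setNames(loo, chroms)
  attr(full, "curve") <- curve
  full
}

#' Convert FST to a divergence-time range
#'
#' Under pure drift, two populations of constant diploid effective size Ne
#' separated for t generations accumulate FST = 1 - exp(-t / (2 Ne)),
#' which is approximately t / (2 Ne) when small.  Inverting gives
#' t = 2 Ne FST (\code{linear}) or t = -2 Ne ln(1 - FST) (\code{log},
#' exact under the drift model).  Supplying a range of effective sizes
#' yields a divergence-time range in years.
#'
#' @param fst fixation index, in [0, 1).
#' @param ne_low,ne_high bounds of the diploid effective population size.
#' @param gen_years generation time in years (default 25).
#' @param formula \code{"linear"} or \code{"log"}.
#' @return an object of class \code{divergence_estimate}: list with
#'   \code{fst}, \code{ne_low}, \code{ne_high}, \code{gen_years},
#'   \code{formula}, \code{t_gens_low}, \code{t_gens_high},
#'   \code{t_years_low}, \code{t_years_high}.
#' @export
fst_to_divergence_time <- function(fst, ne_low, ne_high = ne_low,
                                   gen_years = 25,
                                   formula = c("linear", "log")) {
  formula <- match.arg(formula)
  if (fst < 0) stop("fst must be non-negative")
  if (fst >= 1) stop("fst must be < 1")
  stopifnot(ne_low > 0, ne_high >= ne_low)

  t_of <- function(ne) {
    if (formula == "linear") 2 * ne * fst else -2 * ne * log1p(-fst)
  }
  tg <- c(t_of(ne_low), t_of(ne_high))
  structure(list(fst = fst, ne_low = ne_low, ne_high = ne_high,
                 gen_years = gen_years, formula = formula,
                 t_gens_low = tg[1], t_gens_high = tg[2],
                 t_years_low = tg[1] * gen_years,
                 t_years_high = tg[2] * gen_years),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "divergence_estimate: FST %.4g, Ne %g-%g, %s formula\n  %.0f-%.0f years (%g y/generation)\n",
    x$fst, x$ne_low, x$ne_high, x$formula,
    x$t_years_low, x$t_years_high, x$gen_years))
  invisible(x)
}
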