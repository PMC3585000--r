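---
title: "Population structure, ancestry decomposition and admixture-LD dating with popadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure, ancestry decomposition and admixture-LD dating with popadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popadmix implements the computational core of a genome-wide
population-structure analysis for diploid biallelic SNP data: quality
control and LD pruning, identity-by-state (IBS) distances with classical
multidimensional scaling, variance-normalized PCA with iterative outlier
trimming, likelihood-based ancestry decomposition, dating of admixture
events from the decay of admixture linkage disequilibrium, and conversion
of FST to drift divergence times. This vignette describes the models
behind each stage, the parameters that matter, and the design choices
made where the methods literature leaves them open.

## Data model and quality control

The pipeline currency is a `genotype_dataset`: an N x M matrix of
allele-1 dosages in {0, 1, 2, NA}, a sample table (id, population,
optional subgroup/region), and a SNP map with chromosome, genetic
position in centiMorgans, physical position and the two alleles.
PLINK BED/BIM/FAM (binary, SNP-major) and PED/MAP (text) input and output
are supported. Two representational limits of those formats are worth
knowing: FAM/PED carry only one group label per sample (we use the family
id column for the population), and a PED column with no observed
heterozygote and a single observed allele cannot declare which allele is
allele 1, so such SNPs round-trip only up to allele relabeling. The
binary dialect has neither limitation for genotypes.

`qc_filter()` retains SNPs with missing fraction at most
`max_snp_missing` (default 0.01, i.e. a 99% genotyping success
requirement, with the boundary value retained) and by default drops
non-autosomal SNPs, since X/Y/MT markers follow different inheritance and
would distort autosomal structure statistics. Samples are never removed
and retained genotypes never altered.

`ld_prune()` removes SNPs in strong local LD before structure and
ancestry analysis, because clusters of correlated SNPs would otherwise be
over-weighted. The method literature typically states only an r²
threshold (0.4 here by default); the windowing is our fixed convention:
50-SNP windows advancing by 5 SNPs, and within a window the worst pair
above threshold is broken greedily, dropping the member with more missing
data, then the later one in map order. Both choices are exposed as
parameters; the greedy tie-break makes output reproducible.
Correlations use pairwise-complete observations, and monomorphic SNPs
(undefined r²) are never pruned for LD.

## Structure: IBS-MDS, normalized PCA, outlier trimming

The IBS similarity of two samples is the average fraction of alleles
shared by state over SNPs where both are observed (per SNP,
`1 - |a - b|/2` for dosages a and b); `ibs_distance_matrix()` returns one
minus this. `classical_mds()` is the Torgerson embedding: double-center
the squared distances, eigendecompose, scale eigenvectors by the square
roots of the non-negative eigenvalues. Negative eigenvalues (non-Euclidean
input) are truncated; if fewer positive eigenvalues exist than requested
dimensions, fewer columns are returned with a warning.

`pca_normalized()` divides each centered SNP column by sqrt(p(1-p)) with
p the mean dosage over 2 — the normalization that gives every SNP equal
expected contribution under drift. Missing entries are mean-imputed
(they then contribute nothing after centering); monomorphic columns are
dropped. Components are oriented so the largest-magnitude score is
positive, a pure sign convention for determinism.

`pca_outlier_removal()` iterates PCA and removes samples scoring more
than `sigma` standard deviations from the mean on any of the top `n_pcs`
components, stopping when nothing is removed or after `max_iter` rounds.
The defaults (6 sigma, 10 PCs, 5 iterations) follow the long-standing
smartpca convention. Removal stops rather than reduce a cohort below 3
samples. Once converged, rerunning removes nothing (idempotence), which
the tests assert.

## Ancestry decomposition

The admixture model treats individual i's genotype at SNP m as
Binomial(2, pi_im) with pi_im = sum_k Q_ik P_km: Q holds per-individual
ancestry proportions over K components and P the component allele
frequencies. `fit_admixture()` maximizes this likelihood by the classical
EM updates that alternate expected ancestry-allele counts between Q and
P. The upstream tools use block-relaxation accelerations; we chose plain
EM deliberately — same stationary points, strictly monotone likelihood
(asserted every iteration), and easy to verify. P is clipped to
[1e-6, 1 - 1e-6] to keep the likelihood finite; Q rows are initialized
from a flat Dirichlet and P from observed frequencies plus seeded noise.
Components are relabeled by descending total ancestry mass so output is
deterministic per seed. K = 1 is returned in closed form (observed
frequencies).

`admixture_cv()` selects K by entry-level cross-validation: non-missing
genotype entries are partitioned into folds, each fold is masked to
missing in turn, the model refit, and masked dosages predicted as
2 * sum_k Q_ik P_km. The error is the pooled mean squared deviation — a
deterministic, differentiable choice the upstream literature leaves
unspecified. Fold refits default to 100 EM iterations at tolerance 1e-3
(the full fit defaults to 500 and 1e-4): predictions of held-out dosages
stabilize long before the likelihood's last decimals, so the ranking of
K values is unaffected while the run time drops several-fold. CV error
for every K is reported and the minimum flagged; the choice of K for
interpretation is left to the user, since CV can be flat or misleading
for closely related populations.

`component_fst()` measures differentiation between two rows of P as a
ratio of averages across SNPs (sums before division, never a mean of
per-SNP ratios). Two estimators are provided, Hudson (default) and Nei;
the choice is recorded with the result. A useful calibration, which the
test suite verifies by simulation: for two Balding–Nichols populations
each at drift F from their common ancestor, the Hudson ratio-of-averages
estimator on their frequency rows has expectation F (the between-
population variance 2Fp(1-p) over the expected denominator 2p(1-p)).
On sample frequencies from panels of N diploids the plain estimator is
biased upward by about (1-F)/(2N); panels of a few hundred samples keep
this in the low percent range.

## Dating admixture from LD decay

Admixture between two differentiated populations creates association
between alleles at linked loci; recombination erodes it by a factor
(1 - d) per generation at genetic distance d Morgans, so n generations
after a single pulse the expected admixture LD is proportional to
exp(-n d). `weighted_ld_statistic()` measures this signal: each SNP is
weighted by its allele-frequency difference delta between the two
reference panels, each same-chromosome SNP pair contributes the Pearson
correlation z of its dosages across the admixed cohort, and each distance
bin reports the correlation A(d) between weight products delta_x delta_y
and z over its pairs — a normalization that keeps |A| <= 1 and makes the
statistic invariant to swapping the references. Defaults: 0.1 cM bins to
30 cM, pairs with fewer than 10 complete observations skipped as noise
control. Bins are accumulated per chromosome so the jackknife can reuse
them.

`fit_exponential_decay()` fits A(d) = A0 exp(-n d) (optionally plus a
constant offset) by pair-count-weighted nonlinear least squares with the
rate bounded at zero, over 0.5-30 cM by default — the short-range cutoff
excludes background LD not created by admixture. A perfectly flat curve
is unidentifiable for the exponential-plus-offset model and returns rate
0 with the level in the offset (or amplitude) in closed form. The date in
years is rate x generation time (25 years by default).
`jackknife_date()` re-fits leaving out one chromosome at a time and
reports a delete-one block-jackknife standard error weighted by SNPs per
chromosome.

The instantaneous-pulse model is the only one fitted; under continuous
gene flow the fitted rate is an average of mixture times, and should be
read as such.

## FST and divergence time

Under pure drift at constant diploid effective size Ne, two populations
separated t generations reach FST = 1 - exp(-t/(2 Ne)).
`fst_to_divergence_time()` inverts this either to first order
(t = 2 Ne FST, the `linear` default) or exactly (`log`,
t = -2 Ne ln(1 - FST)); supplying an Ne range yields a year range at the
chosen generation time. The log form dominates the linear one and both
are monotone in FST and Ne. `fst_from_divergence()` is the exact forward
companion, and the pair round-trips to numerical precision. Published
analyses do not always print which form they used, which is why both are
provided and the formula is recorded in the result.

## The simulator and what it does (not) emulate

The generator reproduces exactly the statistical structure the analysis
assumes, so every parameter it recovers has a known truth:

* `simulate_map()` — uniform SNP placement at a constant 1 cM/Mb.
* `simulate_ancestral_freqs()` — ancestral frequency Uniform(0.05, 0.95)
  per SNP (truncated to avoid near-fixed SNPs that destabilize reference
  weights), population frequencies Balding–Nichols Beta draws at drift F.
* `simulate_panel()` — Binomial(2, p) genotypes, linkage equilibrium
  within populations.
* `simulate_admixed()` — per haploid chromosome, ancestry breakpoints as
  a Poisson process of rate n_gens per Morgan, segment ancestries
  Bernoulli(alpha), alleles drawn from the segment ancestry's frequency;
  genotype = sum of two independent haplotypes. This realizes the
  instantaneous-pulse admixture-LD model exactly, with the ground truth
  (alpha, n_gens, realized ancestry fraction, breakpoint counts) recorded
  alongside.

Deliberately absent: coalescent haplotype sharing, mutation, selection,
continuous migration, within-population LD, phasing. Passing tests
therefore show that each method recovers its own model's parameters at
realistic scales — not that real cohorts satisfy those models. Background
LD in real data is the main omission; the 0.5 cM lower fit bound is the
standard mitigation.

Default study conditions used by the validation suite: two-way admixture
with alpha = 0.2 at n = 10, 30 and 100 generations on 10 chromosomes of 1
Morgan with 20,000 SNPs, 400 admixed samples and two reference panels of
200 drawn at drift F = 0.05 each; ancestry decomposition on 2-3
populations at F = 0.1 with 50-75 samples each and 5,000 SNPs; the
divergence round trip at t = 600 generations, Ne = 7,500, M = 50,000 and
panels of 500. These sizes recover decay rates within about 20%,
own-component ancestry above 0.95 and the divergence time within 10%,
while keeping the whole suite to minutes on one core.

## Reproducibility

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state. `run_pipeline()` derives a named substream per stage
from one master seed, so a configuration plus a seed determines every
artifact byte-for-byte (the report contains no timestamps). The
`scripts/acceptance.R` entry point re-runs the validation computations
from scratch for any seed and writes the resulting quantities as JSON.
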