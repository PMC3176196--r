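---
title: "Kernel principal components for region-based association testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel principal components for region-based association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(kpcatest)
library(dplyr)
```

## The testing problem

Single-SNP association scans pay a heavy multiple-testing price and ignore
the correlation (linkage disequilibrium, LD) among nearby markers. A
region-based alternative treats the $M$ SNPs of a gene or candidate region
as one unit: code each individual's genotypes additively, $x_i \in
\{0,1,2\}^M$ counting copies of the coded allele, summarize the region by a
few orthogonal components, and test those components jointly against
case-control status $D \in \{0, 1\}$.

With linear principal components this is the familiar PCA-LRT: take the
first $L$ principal components $PC_1,\dots,PC_L$ of the pooled dosage
matrix and fit

$$\operatorname{logit} \Pr(D = 1) = \beta_0 + \beta_1 PC_1 + \cdots +
\beta_L PC_L,$$

testing $\beta_1 = \cdots = \beta_L = 0$ with a likelihood-ratio test (LRT)
on $L$ degrees of freedom. Linear PCA, however, can only capture linear
structure among dosages. Kernel PCA generalizes it: map the genotype
vectors into a feature space via a kernel $k(x_i, x_j)$ and extract
principal components there, which yields nonlinear functions of the
original dosages while still producing mutually orthogonal scores — so the
logistic model above, with kernel principal components $KPC_1,\dots,KPC_L$
in place of the $PC$s, is free of multicollinearity by construction.
`kpca_lrt()` implements this KPCA-LRT; `pca_lrt()` and
`single_locus_test()` are the comparators.

## Kernel PCA as implemented

Given the $N \times N$ Gram matrix $K_{ij} = k(x_i, x_j)$, feature-space
centering is applied by double centering, $\tilde K = HKH$ with $H = I -
\tfrac1N \mathbf{1}\mathbf{1}'$; the eigenproblem $\tilde K \alpha =
\tilde\lambda \alpha$ then delivers the component directions. Expansion
coefficients are normalized so each feature-space direction has unit norm,
$\tilde\lambda_k\, (\alpha^k \cdot \alpha^k) = 1$, which makes the $k$-th
score column equal $\sqrt{\tilde\lambda_k}$ times the unit eigenvector; its
sum of squares equals $\tilde\lambda_k$, an identity the test suite checks
directly. Components are ordered by decreasing eigenvalue and $L$ is the
smallest number whose cumulative share of the positive spectrum reaches the
threshold (default 80%, the conventional choice for PC regression on SNP
sets; the same rule and threshold are used for PCA and KPCA so the two
tests differ only in the component construction).

Numerical choices worth stating:

* **Eigenvalue floor.** Double centering guarantees at least one zero
  eigenvalue, and round-off produces tiny negative ones. Eigenvalues below
  $10^{-10}\,\tilde\lambda_{\max}$ are discarded before variance fractions
  are formed, so the 80% rule runs over the positive spectrum only. For
  KPCA the variance denominator is the sum of retained positive eigenvalues
  of $\tilde K$ (the matrix has up to $N - 1$ of them, not $M$).
* **Sign convention.** An eigenvector's sign is arbitrary; each score
  column is flipped so its largest-magnitude entry is positive, making
  output reproducible across eigensolvers. Sign flips cannot change the
  LRT, which is invariant under any invertible affine map of the scores.
* **Ties** are broken by the stable order LAPACK returns; exact ties are
  measure-zero for the data considered here.
* **Duplicate collapsing.** Dosage vectors are discrete, so at study sample
  sizes many individuals share a genotype row. All supported kernels depend
  on individuals only through their rows, so `kpca_scores()` collapses the
  $N$ rows to the $U$ distinct ones and solves an exactly equivalent
  $U \times U$ eigenproblem: with $Z$ the $N \times U$ membership matrix,
  $W = Z'Z$ and $q = \sqrt{\operatorname{diag} W}$, the nonzero spectrum of
  $HZK_uZ'H$ equals that of $PAP$ where $A = W^{1/2} K_u W^{1/2}$ and $P =
  I - qq'/N$, and a unit eigenvector $\beta$ of $PAP$ maps to the unit
  eigenvector $HZW^{-1/2}\beta$ of the full problem. This is an algebraic
  identity, not an approximation; the suite verifies equality with the
  dense route to $10^{-7}$. `kpca()` retains the dense route for an
  explicit Gram matrix.
* **Degenerate inputs.** A region whose rows are all identical has no
  positive eigenvalue (and no finite median bandwidth) and raises an error;
  monomorphic SNPs are removed by `qc_filter()` before analysis.

### Kernels and the bandwidth

Three kernels are provided: linear ($x_i \cdot x_j$; KPCA then reproduces
linear PCA exactly, a cross-check the tests exploit), the Gaussian RBF
kernel, and the identity-by-state kernel (mean proportion of alleles shared
IBS). The RBF kernel is the default, with bandwidth $\sigma$ set by the
median heuristic: the median of all $N(N-1)/2$ pairwise Euclidean distances
$\lVert x_i - x_j\rVert$, $i < j$, recomputed on each analyzed dataset
(per replicate in simulation) since it is a statistic of the sample.
Self-distances are excluded — they are identically zero and would bias the
median low. If the median itself is zero (a majority of duplicated rows)
the mean positive distance is used. Cross-validated bandwidth selection is
deliberately out of scope: it multiplies the computation by the fold count
and is unnecessary for a test whose size the simulations confirm.

The RBF exponent convention is $k(x, y) = \exp(-\lVert x-y\rVert^2 /
(2\sigma^2))$, the parameterization under which the median-heuristic
literature states the rule; the alternative $\exp(-\lVert x - y\rVert^2 /
\sigma^2)$ is available as `rbf_form = "sigma2"` for comparison with
implementations that use it. Centering can likewise be disabled
(`center = FALSE`) to probe its effect; the default is to center, which is
the exact feature-space treatment for training data.

## The likelihood-ratio test

`logistic_lrt()` fits the full logistic model by maximum likelihood
(iteratively reweighted least squares via `glm.fit`) and compares its
deviance with the intercept-only model; the statistic is referred to
$\chi^2_L$. Because the components are extracted from the pooled sample,
blind to phenotype, the chi-square reference is asymptotically valid
without permutation correction. Replicates with a non-converged or
separated fit report `converged = FALSE` and a missing p-value, and the
study runner excludes them from rejection-rate denominators while counting
them — at the sample sizes studied here they essentially never occur. The
single-locus comparator runs a 1-df additive logistic LRT per SNP and
summarizes the region by the raw minimum p-value, with the Bonferroni
minimum reported alongside, since no aggregation convention is canonical
for this comparator.

## What the simulator emulates

`make_haplotype_pool()` and `sample_case_control()` stand in for the usual
pipeline of resampling phased reference haplotypes with a disease model.
The default region mimics an 11-SNP candidate-gene panel organized in three
haplotype blocks (sizes 4/4/3): haplotypes are drawn by thresholding a
latent Gaussian vector with block-diagonal equicorrelation (0.8 within
blocks, independence across), each column dichotomized at the upper
quantile matching its target minor allele frequency. The default MAF
targets span 0.10–0.45, the common-variant range, with values fixed once
per block (see `default_maf_targets()`); the latent correlation 0.8 gives
haplotype-allele $r^2$ around 0.3–0.6 within blocks, the shape of a typical
strong-LD candidate region. The tetrachoric relationship between latent
correlation and realized allele correlation is verified in the tests
against numerically integrated bivariate-normal orthant probabilities.
Individuals are formed by drawing two haplotypes with replacement
(Hardy–Weinberg pairing).

Disease status follows a multiplicative per-allele model at one designated
causal SNP (default the 6th): under the rare-disease approximation, case
probability is proportional to $RR^g$ with $g$ the causal risk-allele
count, which factorizes over haplotypes, so case haplotypes are sampled
with weight $RR$ when they carry the risk allele. Controls are drawn from
the population distribution. The causal column is then **removed** from the
returned matrix, so the tests must detect the signal indirectly through LD
— the harder and more realistic design. `RR = 1` gives the null for type-I
error; the power grid uses the small effect sizes (1.1–1.5 per allele)
typical of common-variant association.

What the generator does *not* emulate: recombination-gradient LD decay
within blocks (equicorrelation is flat), rare variants (MAF below 0.05),
multiple causal SNPs, genotyping error or missingness (simulated data are
complete; mean imputation exists only for the real-data readers), and
population stratification. Passing calibration here therefore shows the
test machinery is sound under clean HWE data with block LD, not that the
method is robust to those complications.

## Reproducibility and study sizes

`run_study()` derives the pool seed and one seed per replicate from the
master seed up front, making a study a pure function of its configuration
and any single replicate re-runnable in isolation from its logged seed.
Default study sizes are desk-scale: 1000 replicates at 500 cases / 500
controls. The suite's calibration block runs at total $N = 1000$ with 1000
replicates, p-value uniformity pools 2000 replicates at $N = 500$, and the
power curves use $N = 1000$ with 500 replicates per relative-risk level.
These sizes put three binomial standard errors at a nominal 0.05 level
around $\pm 0.015$ to $\pm 0.021$, tight enough to detect meaningful
miscalibration; larger designs are reachable through `sim_config()`. One
caveat the calibration sizes reflect: the $\chi^2_L$ reference is
asymptotic, and with the RBF kernel $L$ runs around a dozen components, so
at small sample sizes relative to $L$ the LRT drifts slightly liberal —
sample sizes in the hundreds per arm are where the nominal level is
trustworthy.

```{r example}
cfg <- sim_config(n_cases = 100, n_controls = 100, replicates = 20, seed = 9)
study <- run_study(cfg)
tidy(study)
```

## Known limitations

* Binary phenotypes only: the LRT is logistic, so quantitative traits are
  out of scope.
* No covariate adjustment; components are tested alone.
* The region is analyzed as given — no sliding windows, no genome-wide
  loop, no gene annotation handling.
* Kernel choice remains the user's: the RBF default with the median
  heuristic behaves well across the simulated designs, but no data-driven
  kernel selection is attempted.
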