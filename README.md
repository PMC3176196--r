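# kpcatest

Gene- and region-based case-control association testing for SNP sets via
kernel principal component analysis combined with a logistic-regression
likelihood-ratio test (KPCA-LRT), with linear PCA-LRT and a single-locus
scan as comparators, and a haplotype-pool simulator for type-I-error and
power studies.

## The method

For a region of $M$ SNPs coded additively ($x_i \in \{0,1,2\}^M$ counting
copies of the coded allele), a kernel $k(x_i, x_j)$ — by default the
Gaussian RBF kernel $\exp(-\lVert x_i - x_j \rVert^2 / 2\sigma^2)$ with
$\sigma$ set to the median pairwise Euclidean distance in the sample —
defines an implicit feature space. Kernel PCA double-centers the Gram
matrix $K$, solves $\tilde K\alpha = \tilde\lambda\alpha$, normalizes so
each feature-space direction has unit norm, and keeps the first $L$
components that explain 80% of the (positive) spectrum. The retained
scores enter a logistic regression

$$\operatorname{logit} \Pr(D=1) = \beta_0 + \beta_1\,KPC_1 + \cdots +
\beta_L\,KPC_L,$$

and the region-level p-value is the likelihood-ratio statistic against the
intercept-only model on $\chi^2_L$. Because kernel principal components
are mutually orthogonal, the model is free of the multicollinearity that
afflicts joint per-SNP regressions; because the kernel is nonlinear, the
components can capture structure linear PCA misses. With the linear kernel
the procedure reduces exactly to PCA-LRT.

The simulator generates an LD-structured haplotype pool (latent-Gaussian
dichotomization: 11 SNPs in three blocks by default), assigns disease by a
multiplicative per-allele relative risk at a designated causal SNP, and
removes the causal SNP before testing, so association is detected
indirectly through LD.

## Worked example

```r
library(kpcatest)

# a simulated region: 11 SNPs, three LD blocks, causal SNP 6 removed,
# per-allele relative risk 1.5, 500 cases / 500 controls
cfg  <- sim_config(relative_risk = 1.5, n_cases = 500, n_controls = 500,
                   replicates = 1, seed = 42)
pool <- make_haplotype_pool(cfg)
dat  <- sample_case_control(pool, cfg, seed = 43)

region_test(dat, threshold = 0.8)
#> <region_result> 10 SNPs
#> <assoc_test> kpca_lrt: LRT = 28.936 on 13 df, p = 0.006684
#> <assoc_test> pca_lrt: LRT = 23.529 on 5 df, p = 0.0002673
#> <assoc_test> single_locus: LRT = 18.076 on 1 df, p = 2.122e-05
```

All three tests detect the removed causal variant through its LD partners:
KPCA-LRT spends 13 df on the kernel components it needs to reach 80%
variance, PCA-LRT 5, and the single-locus line is the raw minimum per-SNP
p-value (Bonferroni-adjusted copy in `$p_bonferroni`). Results convert to
tibbles with `tidy()`; a replicated study does the same:

```r
study <- run_study(sim_config(n_cases = 250, n_controls = 250,
                              replicates = 200, seed = 7))
tidy(study)
#> # A tibble: 4 × 5
#>   method   alpha n_used rejections   rate
#>   <chr>    <dbl>  <int>      <int>  <dbl>
#> 1 kpca_lrt  0.01    200          3 0.015
#> 2 kpca_lrt  0.05    200          9 0.045
#> 3 pca_lrt   0.01    200          0 0
#> 4 pca_lrt   0.05    200         10 0.05
```

Under the null (relative risk 1.0, the default) both methods reject at
close to the nominal rate. `autoplot(study)` and `plot_calibration(study)`
draw the rejection-rate and p-value-uniformity diagnostics.

Real data enter through `read_vcf()` / `read_genotype_tsv()` +
`read_phenotype_tsv()` and `qc_filter()`, or from the shell via the thin
wrapper:

```sh
Rscript inst/cli/kpcatest.R test --vcf region.vcf --pheno pheno.tsv \
    --method kpca --kernel rbf --sigma median --threshold 0.8 --out results/
```

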