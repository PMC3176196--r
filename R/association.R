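#' Association test results
#'
#' Every test returns an `assoc_test` object holding the likelihood-ratio
#' statistic (deviance difference between the full and the intercept-only
#' logistic model), its degrees of freedom, the upper-tail chi-square
#' p-value, the fitted coefficients and a convergence flag. Use [tidy()] for
#' a one-row tibble and [glance()] for fit-level summaries.
#'
#' @name assoc_test
#' @keywords internal
NULL

new_assoc_test <- function(method, statistic, df, p_value, L, beta,
                           converged, n_cases, n_controls, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, L = L, beta = beta, converged = converged,
           n_cases = n_cases, n_controls = n_controls), extra),
    class = "assoc_test"
  )
}

#' @export
print.assoc_test <- function(x, ...) {
  cat("<assoc_test> ", x$method,
      ": LRT = ", format(x$statistic, digits = 5),
      " on ", x$df, " df, p = ", format.pval(x$p_value, digits = 4),
      if (!x$converged) "  [did not converge]" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.assoc_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p_value = x$p_value, L = x$L, converged = x$converged)
}

#' @export
glance.assoc_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p_value = x$p_value, L = x$L, converged = x$converged,
         n_cases = x$n_cases, n_controls = x$n_controls)
}

# deviance-based logistic LRT of y on the columns of X (plus intercept)
# against the intercept-only model
lrt_core <- function(X, y) {
  n <- length(y)
  k <- sum(y)
  null_dev <- -2 * (k * log(k / n) + (n - k) * log1p(-k / n))
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
  stat <- null_dev - fit$deviance
  stat <- max(stat, 0)  # clip tiny negative round-off
  df <- ncol(Xd) - 1L
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary)
  p <- if (converged) pchisq(stat, df = df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p,
       beta = fit$coefficients, converged = converged)
}

#' Likelihood-ratio test of components against case-control status
#'
#' Fits the logistic model
#' `logit Pr(D = 1) = beta_0 + beta_1 C_1 + ... + beta_L C_L`
#' by maximum likelihood, where `C_1..C_L` are the retained (kernel)
#' principal component scores, and compares it to the intercept-only model.
#' The statistic is the deviance difference, referred to a chi-square
#' distribution with `L` degrees of freedom.
#'
#' @param scores A `component_scores` object ([pca_scores()],
#'   [kpca_scores()]).
#' @param pheno A phenotype tibble (`iid`, `status`); matched to the scores
#'   by `iid`.
#' @return An `assoc_test`.
#' @export
logistic_lrt <- function(scores, pheno) {
  stopifnot(inherits(scores, "component_scores"))
  validate_phenotypes(pheno)
  geno_like <- tibble(iid = scores$iid)
  y <- align_phenotype(geno_like, pheno)
  fit <- lrt_core(scores$scores, y)
  new_assoc_test(
    method = paste0(scores$method, "_lrt"),
    statistic = fit$statistic, df = fit$df, p_value = fit$p_value,
    L = scores$L, beta = fit$beta, converged = fit$converged,
    n_cases = sum(y == 1L), n_controls = sum(y == 0L)
  )
}

#' PCA-based region association test (PCA-LRT)
#'
#' Extracts linear principal components of the dosage matrix
#' ([pca_scores()]) and jointly tests the retained components against
#' case-control status with [logistic_lrt()]. Component extraction is
#' phenotype-blind: it uses the pooled sample.
#'
#' @inheritParams kpca_scores
#' @param pheno Phenotype tibble (`iid`, `status`); may be `NULL` when
#'   `geno` itself carries a `status` column.
#' @return An `assoc_test`.
#' @export
pca_lrt <- function(geno, pheno = NULL, threshold = 0.8) {
  dat <- resolve_data(geno, pheno)
  scores <- pca_scores(strip_status(geno), threshold)
  fit <- lrt_core(scores$scores, dat$y)
  new_assoc_test("pca_lrt", fit$statistic, fit$df, fit$p_value,
                 L = scores$L, beta = fit$beta, converged = fit$converged,
                 n_cases = sum(dat$y == 1L), n_controls = sum(dat$y == 0L))
}

#' Kernel-PCA region association test (KPCA-LRT)
#'
#' Computes the configured genotype kernel (by default RBF with the
#' median-heuristic bandwidth, resolved on this dataset), extracts kernel
#' principal components, and jointly tests the retained components against
#' case-control status with a likelihood-ratio test on `L` degrees of
#' freedom. With a linear kernel this reproduces [pca_lrt()] exactly.
#'
#' @inheritParams pca_lrt
#' @param kernel A [kernel_config()].
#' @param center Center the kernel in feature space (default `TRUE`).
#' @return An `assoc_test`; the resolved RBF bandwidth is reported in
#'   `$sigma` when applicable.
#' @export
kpca_lrt <- function(geno, pheno = NULL, kernel = kernel_config(),
                     threshold = 0.8, center = TRUE) {
  dat <- resolve_data(geno, pheno)
  scores <- kpca_scores(strip_status(geno), kernel, threshold, center)
  fit <- lrt_core(scores$scores, dat$y)
  new_assoc_test("kpca_lrt", fit$statistic, fit$df, fit$p_value,
                 L = scores$L, beta = fit$beta, converged = fit$converged,
                 n_cases = sum(dat$y == 1L), n_controls = sum(dat$y == 0L),
                 extra = list(kernel = kernel$kernel,
                              sigma = attr(scores, "sigma")))
}

strip_status <- function(geno) geno[setdiff(names(geno), "status")]

#' Single-locus comparator test
#'
#' Tests each SNP separately with a 1-df additive logistic likelihood-ratio
#' test and summarizes the region by the minimum per-SNP p-value (reported
#' raw, with the Bonferroni-adjusted minimum alongside). SNPs whose fit does
#' not converge are excluded from the minimum.
#'
#' @inheritParams pca_lrt
#' @return An `assoc_test` whose `p_value` is the raw minimum per-SNP
#'   p-value; `$p_bonferroni` holds `min(1, M * min p)` and `$per_snp` a
#'   tibble of per-SNP statistics.
#' @export
single_locus_test <- function(geno, pheno = NULL) {
  dat <- resolve_data(geno, pheno)
  X <- dat$X
  y <- dat$y
  per <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    f <- lrt_core(X[, j, drop = FALSE], y)
    tibble(snp = colnames(X)[j], statistic = f$statistic,
           p_value = if (f$converged) f$p_value else NA_real_,
           converged = f$converged)
  })
  ok <- !is.na(per$p_value)
  if (!any(ok)) abort("no single-SNP fit converged")
  pmin_raw <- min(per$p_value[ok])
  best <- per$snp[ok][which.min(per$p_value[ok])]
  m <- ncol(X)
  new_assoc_test(
    "single_locus",
    statistic = max(per$statistic[ok]), df = 1L,
    p_value = pmin_raw, L = NA_integer_, beta = NULL,
    converged = all(per$converged),
    n_cases = sum(y == 1L), n_controls = sum(y == 0L),
    extra = list(p_bonferroni = min(1, m * pmin_raw),
                 best_snp = best, snp_count = m, per_snp = per)
  )
}

#' Run several region tests on one dataset
#'
#' Convenience wrapper running any of `"kpca"`, `"pca"` and `"single"` on
#' the same genotype/phenotype pair and collecting the results.
#'
#' @inheritParams kpca_lrt
#' @param methods Character vector of tests to run.
#' @return A `region_result`: a list of `assoc_test`s with a [tidy()] method
#'   returning one row per test.
#' @export
region_test <- function(geno, pheno = NULL,
                        methods = c("kpca", "pca", "single"),
                        kernel = kernel_config(), threshold = 0.8) {
  methods <- match.arg(methods, several.ok = TRUE)
  tests <- list()
  if ("kpca" %in% methods) {
    tests$kpca <- kpca_lrt(geno, pheno, kernel, threshold)
  }
  if ("pca" %in% methods) tests$pca <- pca_lrt(geno, pheno, threshold)
  if ("single" %in% methods) tests$single <- single_locus_test(geno, pheno)
  structure(list(tests = tests,
                 snp_count = ncol(geno_matrix(geno))),
            class = "region_result")
}

#' @export
print.region_result <- function(x, ...) {
  cat("<region_result> ", x$snp_count, " SNPs\n", sep = "")
  for (t in x$tests) print(t)
  invisible(x)
}

#' @export
tidy.region_result <- function(x, ...) {
  purrr::map_dfr(x$tests, tidy)
}
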