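# Shared fixtures and independent oracles used across the suite.

# Random genotype tibble: m SNPs drawn binomial(2, maf) per column
# (Hardy-Weinberg, no LD), with a deterministic seed.
random_genotypes <- function(n, m, seed, mafs = NULL) {
  withr::with_seed(seed, {
    if (is.null(mafs)) mafs <- runif(m, 0.1, 0.5)
    X <- sapply(seq_len(m), function(j) rbinom(n, 2L, mafs[j]))
    X <- matrix(as.numeric(X), nrow = n)
    colnames(X) <- sprintf("snp%02d", seq_len(m))
    dplyr::bind_cols(tibble::tibble(iid = sprintf("i%03d", seq_len(n))),
                     tibble::as_tibble(X))
  })
}

random_phenotypes <- function(geno, seed, p = 0.5) {
  withr::with_seed(seed, {
    s <- integer(nrow(geno))
    while (sum(s) < 1 || sum(s) > length(s) - 1) {
      s <- rbinom(nrow(geno), 1L, p)
    }
    tibble::tibble(iid = geno$iid, status = s)
  })
}

# Independent logistic maximum-likelihood oracle: coarse grid over
# (beta0, beta1) followed by Nelder-Mead/BFGS refinement of the negative
# log-likelihood, entirely separate from glm.fit / IRLS.
oracle_logistic_lrt_1d <- function(x, y) {
  stopifnot(length(x) == length(y))
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  n <- length(y); k <- sum(y)
  nll0 <- -(k * log(k / n) + (n - k) * log((n - k) / n))
  grid <- expand.grid(b0 = seq(-6, 6, by = 0.25),
                      b1 = seq(-8, 8, by = 0.25))
  vals <- apply(grid, 1L, nll)
  best <- as.numeric(grid[which.min(vals), ])
  o1 <- optim(best, nll, method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 5000))
  o2 <- optim(o1$par, nll, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  nll_full <- min(o1$value, o2$value)
  2 * (nll0 - nll_full)
}

# Dense reference eigendecomposition of the doubly centered Gram matrix,
# written straight from the definition (independent of the package path).
oracle_centered_eigen <- function(K) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kt <- H %*% K %*% H
  list(Kt = Kt, eig = eigen((Kt + t(Kt)) / 2, symmetric = TRUE))
}

# Bivariate-normal upper-orthant probability P(X > t, Y > t) at correlation
# rho, by 1-D numerical integration of the conditional normal.
oracle_orthant_prob <- function(t, rho) {
  f <- function(x) dnorm(x) * pnorm((rho * x - t) / sqrt(1 - rho^2))
  integrate(f, t, Inf, rel.tol = 1e-10)$value
}

# binomial Monte-Carlo standard error
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
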