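test_that("kernel centering equals the double-centering projector", {
  # N = 1: any value centers to zero
  expect_equal(unname(center_kernel(matrix(3.7))$values), matrix(0))

  # 2x2 identity: hand evaluation of H K H
  expect_equal(unname(center_kernel(diag(2))$values),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  # row/column sums vanish and it matches the explicit H K H product
  for (seed in 1:4) {
    g <- random_genotypes(10, 4, seed = seed)
    K <- rbf_kernel(g, sigma = "median")$values
    Kc <- center_kernel(K)$values
    expect_lt(max(abs(rowSums(Kc))), 1e-10)
    expect_lt(max(abs(colSums(Kc))), 1e-10)
    expect_equal(unname(Kc), oracle_centered_eigen(K)$Kt,
                 tolerance = 1e-12)
  }
})

test_that("component count is the smallest L reaching the threshold", {
  expect_equal(select_num_components(c(5, 3, 1, 1), 0.8), 2L)
  expect_equal(select_num_components(c(4, 3, 2, 1), 0.8), 3L)
  expect_equal(select_num_components(7, 0.99), 1L)
  expect_equal(select_num_components(c(4, 3, 2, 1), 1), 4L)
  expect_error(select_num_components(numeric(0), 0.8), "no eigenvalues")
  expect_error(select_num_components(c(1, 2), 0.8), "decreasing")
})

test_that("KPCA satisfies the eigen-residual and normalization identities", {
  for (seed in 1:5) {
    g <- random_genotypes(14, 5, seed = seed)
    K <- rbf_kernel(g, sigma = "median")
    cs <- kpca(K, threshold = 1)   # keep all positive components
    orc <- oracle_centered_eigen(K$values)
    Kt <- orc$Kt
    for (k in seq_len(cs$L)) {
      lam <- cs$eigenvalues[k]
      # per-component score sum of squares equals the eigenvalue
      expect_equal(sum(cs$scores[, k]^2), lam, tolerance = 1e-8)
      # unit eigenvector residual of the centered Gram matrix
      a <- cs$scores[, k] / sqrt(lam)
      expect_lt(max(abs(Kt %*% a - lam * a)), 1e-8 * norm(Kt, "2"))
    }
    # eigenvalues positive, non-increasing; fractions sum to 1 at threshold 1
    expect_true(all(diff(cs$eigenvalues) <= 1e-12))
    expect_gt(min(cs$eigenvalues), 0)
    expect_equal(sum(cs$variance_fractions), 1, tolerance = 1e-10)
  }
})

test_that("two distinct points give one positive component with symmetric scores", {
  g <- dplyr::bind_cols(tibble::tibble(iid = c("a", "b")),
                        tibble::as_tibble(rbind(c(0, 0), c(2, 1)),
                                          .name_repair = ~c("s1", "s2")))
  cs <- kpca(rbf_kernel(g, sigma = 1), threshold = 0.8)
  expect_equal(cs$total_components_available, 1L)
  expect_equal(cs$L, 1L)
  expect_equal(cs$scores[1, 1], -cs$scores[2, 1])
})

test_that("linear-kernel KPCA reproduces linear PCA up to column signs", {
  for (seed in 1:5) {
    g <- random_genotypes(20, 6, seed = seed)
    p <- pca_scores(g, threshold = 0.8)
    k <- kpca(linear_kernel(g), threshold = 0.8)
    expect_equal(k$L, p$L)
    expect_equal(unname(abs(k$scores)), unname(abs(p$scores)),
                 tolerance = 1e-8)
    expect_equal(k$variance_fractions, p$variance_fractions,
                 tolerance = 1e-10)
  }
})

test_that("PCA scores are orthogonal, centered projections of the dosages", {
  g <- random_genotypes(25, 6, seed = 3)
  p <- pca_scores(g, threshold = 1)
  S <- p$scores
  G <- crossprod(S)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_lt(max(abs(colMeans(S))), 1e-10)

  # M = 1: the single component is the centered genotype column (up to sign)
  g1 <- g[c("iid", "snp01")]
  p1 <- pca_scores(g1, threshold = 0.8)
  expect_equal(p1$L, 1L)
  expect_equal(abs(p1$scores[, 1]),
               abs(g1$snp01 - mean(g1$snp01)), tolerance = 1e-10)
})

test_that("fast duplicate-collapsing KPCA equals the dense route exactly", {
  for (seed in 1:4) {
    g <- random_genotypes(60, 4, seed = seed)  # many duplicated dosage rows
    for (cfg in list(kernel_config("rbf", sigma = "median"),
                     kernel_config("linear"),
                     kernel_config("ibs"))) {
      fast <- kpca_scores(g, cfg, threshold = 0.9)
      Kd <- compute_kernel(g, cfg)
      dense <- kpca(Kd, threshold = 0.9)
      expect_equal(fast$L, dense$L)
      expect_equal(fast$scores, dense$scores, tolerance = 1e-7)
      expect_equal(fast$eigenvalues, dense$eigenvalues, tolerance = 1e-8)
    }
  }
})

test_that("scores are equivariant under permuting individuals", {
  g <- random_genotypes(30, 5, seed = 11)
  perm <- withr::with_seed(2, sample(nrow(g)))
  cs <- kpca_scores(g, kernel_config("rbf", sigma = 1.5), 0.8)
  csp <- kpca_scores(g[perm, ], kernel_config("rbf", sigma = 1.5), 0.8)
  expect_equal(csp$eigenvalues, cs$eigenvalues, tolerance = 1e-9)
  expect_equal(csp$variance_fractions, cs$variance_fractions,
               tolerance = 1e-9)
  expect_equal(abs(csp$scores), abs(cs$scores[perm, , drop = FALSE]),
               tolerance = 1e-7)
})

test_that("KPCA agrees with an independent kernel-PCA implementation", {
  skip_if_not_installed("kernlab")
  g <- random_genotypes(30, 6, seed = 21)
  X <- as.matrix(g[-1])
  sig <- 2.0
  cs <- kpca(rbf_kernel(g, sigma = sig), threshold = 1)
  kl <- kernlab::kpca(X, kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * sig^2)), features = 0)
  scl <- kernlab::rotated(kl)
  for (k in 1:3) {
    expect_equal(abs(cor(cs$scores[, k], scl[, k])), 1, tolerance = 1e-6)
  }
})

test_that("out-of-sample projection reproduces training scores", {
  g <- random_genotypes(18, 4, seed = 5)
  p <- pca_scores(g, threshold = 0.9)
  expect_equal(unname(predict(p, g)), unname(p$scores), tolerance = 1e-10)

  K <- rbf_kernel(g, sigma = 1.7)
  ck <- kpca(K, threshold = 0.9)
  expect_equal(unname(predict(ck, K$values)), unname(ck$scores),
               tolerance = 1e-8)
})

test_that("tidiers expose scores and fit summaries as tibbles", {
  g <- random_genotypes(12, 4, seed = 8)
  cs <- kpca_scores(g, kernel_config("rbf", sigma = 1), 0.8)
  td <- tidy(cs)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iid", "component", "score"))
  expect_equal(nrow(td), nrow(g) * cs$L)
  gl <- glance(cs)
  expect_equal(gl$L, cs$L)
  expect_gte(gl$variance_explained, 0.8)
})
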