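#' Center a Gram matrix in feature space
#'
#' Kernel PCA assumes the mapped observations have zero mean in feature
#' space. For training data this is achieved by double centering,
#' `K~ = H K H` with `H = I - (1/N) 11'`, which makes every row and column of
#' the result sum to zero.
#'
#' @param K A `kernel_matrix` (or plain symmetric matrix).
#' @return A `kernel_matrix` holding the centered Gram matrix.
#' @export
center_kernel <- function(K) {
  km <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  rm <- rowMeans(km)
  gm <- mean(km)
  Kc <- km - outer(rm, rep(1, ncol(km))) -
    outer(rep(1, nrow(km)), rm) + gm
  new_kernel_matrix(
    Kc,
    if (inherits(K, "kernel_matrix")) paste0("centered_", K$kernel)
    else "centered",
    if (inherits(K, "kernel_matrix")) K$params else list()
  )
}

#' Choose the number of components by cumulative variance
#'
#' Returns the smallest `L` such that the first `L` eigenvalues account for
#' at least `threshold` of their total, the usual
#' `(lambda_1 + ... + lambda_L) / (lambda_1 + ... + lambda_M) >= threshold`
#' rule with the conventional 80% default.
#'
#' @param eigenvalues Positive eigenvalues sorted in decreasing order.
#' @param threshold Fraction in `(0, 1]`.
#' @return Integer `L >= 1`.
#' @export
#' @examples
#' select_num_components(c(5, 3, 1, 1), 0.8)  # 2
select_num_components <- function(eigenvalues, threshold = 0.8) {
  if (length(eigenvalues) == 0L) abort("no eigenvalues to select from")
  if (any(eigenvalues <= 0)) abort("eigenvalues must be positive")
  if (is.unsorted(rev(eigenvalues))) {
    abort("eigenvalues must be sorted in decreasing order")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  frac <- cumsum(eigenvalues) / sum(eigenvalues)
  # guard against round-off at threshold = 1
  frac[length(frac)] <- 1
  which(frac >= threshold - 1e-12)[1L]
}

# ---- component_scores -------------------------------------------------------

new_component_scores <- function(iid, scores, eigenvalues, variance_fractions,
                                 total_available, method, threshold,
                                 projector = NULL) {
  L <- ncol(scores)
  colnames(scores) <- paste0(if (method == "kpca") "KPC" else "PC",
                             seq_len(L))
  structure(
    list(iid = iid, scores = scores, L = L,
         eigenvalues = eigenvalues,
         variance_fractions = variance_fractions,
         total_components_available = total_available,
         method = method, threshold = threshold,
         projector = projector),
    class = "component_scores"
  )
}

#' @export
print.component_scores <- function(x, ...) {
  cat("<component_scores> ", x$method, ": N = ", nrow(x$scores),
      ", L = ", x$L, " of ", x$total_components_available,
      " (", round(100 * sum(x$variance_fractions), 1),
      "% of variance at threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.component_scores <- function(x, ...) {
  dplyr::bind_cols(tibble(iid = x$iid), as_tibble(x$scores))
}

#' @export
tidy.component_scores <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"iid", names_to = "component", values_to = "score")
}

#' @export
glance.component_scores <- function(x, ...) {
  tibble(method = x$method, n = nrow(x$scores), L = x$L,
         total_components_available = x$total_components_available,
         variance_explained = sum(x$variance_fractions),
         threshold = x$threshold)
}

# flip each column so its largest-magnitude entry is positive
fix_signs <- function(S) {
  for (k in seq_len(ncol(S))) {
    i <- which.max(abs(S[, k]))
    if (S[i, k] < 0) S[, k] <- -S[, k]
  }
  S
}

EIG_FLOOR <- 1e-10  # relative floor below which eigenvalues count as zero

# ---- kernel PCA (dense path, from an explicit Gram matrix) ------------------

#' Kernel principal component scores from a Gram matrix
#'
#' Centers `K`, solves the eigenproblem of the centered Gram matrix,
#' normalizes each eigenvector `alpha` so that the corresponding feature-space
#' direction has unit norm (`lambda * (alpha . alpha) = 1`), and returns the
#' training-sample projections. Component `k`'s scores therefore have a sum
#' of squares equal to the `k`-th eigenvalue of the centered Gram matrix.
#' The number of retained components `L` is chosen by
#' [select_num_components()] over the positive eigenvalues.
#'
#' @param K A `kernel_matrix` (uncentered Gram matrix of the sample).
#' @param threshold Cumulative-variance threshold in `(0, 1]`, default `0.8`.
#' @param center Center the kernel in feature space first (default `TRUE`).
#'   `FALSE` eigendecomposes the raw Gram matrix, for probing the effect of
#'   the centering assumption.
#' @return A `component_scores` object.
#' @export
kpca <- function(K, threshold = 0.8, center = TRUE) {
  km <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  iid <- rownames(km) %||% as.character(seq_len(nrow(km)))
  Kc <- if (center) center_kernel(km)$values else km
  e <- eigen(Kc, symmetric = TRUE)
  lam <- e$values
  keep <- lam > EIG_FLOOR * max(lam, 0)
  if (!any(keep)) abort("centered kernel has no positive eigenvalues")
  lam <- lam[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  L <- select_num_components(lam, threshold)
  S <- fix_signs(sweep(vecs[, seq_len(L), drop = FALSE], 2L,
                       sqrt(lam[seq_len(L)]), `*`))
  # alpha (Eq.-style normalized expansion coefficients) for projection:
  # alpha_k = unit eigenvector / sqrt(lambda_k); recover from signed scores
  alpha <- sweep(S, 2L, lam[seq_len(L)], `/`)
  proj <- list(type = "kpca", alpha = alpha,
               train_row_means = rowMeans(km), train_grand_mean = mean(km),
               centered = center)
  vf <- lam / sum(lam)
  new_component_scores(iid, S, lam[seq_len(L)], vf[seq_len(L)],
                       total_available = length(lam),
                       method = "kpca", threshold = threshold,
                       projector = proj)
}

# ---- kernel PCA (fast exact path, from genotype rows) -----------------------

# Kernel evaluated between rows of Xu (and optionally against Y)
kernel_gram_rows <- function(X, config, sigma = NULL, Y = NULL) {
  Y <- Y %||% X
  switch(config$kernel,
    linear = tcrossprod(X, Y),
    rbf = {
      denom <- if (config$rbf_form == "half_sigma2") 2 * sigma^2 else sigma^2
      exp(-row_sqdist(X, Y) / denom)
    },
    ibs = {
      M <- ncol(X)
      D1 <- matrix(0, nrow(X), nrow(Y))
      for (m in seq_len(M)) D1 <- D1 + abs(outer(X[, m], Y[, m], `-`))
      1 - D1 / (2 * M)
    })
}

# Exact KPCA that collapses duplicated genotype rows before the
# eigendecomposition. With U unique rows, Z the N x U membership indicator,
# W = diag(counts) and K = Z Ku Z', the nonzero spectrum of the doubly
# centered H K H equals that of C = P A P with A = W^(1/2) Ku W^(1/2),
# q = sqrt(counts) and P = I - q q' / N; a unit eigenvector beta of C maps to
# the unit eigenvector H Z W^(-1/2) beta of H K H. Discrete dosage data makes
# U much smaller than N, so the U x U eigenproblem is the whole cost.
kpca_engine <- function(X, config = kernel_config(), threshold = 0.8,
                        center = TRUE) {
  N <- nrow(X)
  if (N < 2L) abort("need at least two individuals")
  sigma <- NULL
  u <- unique_rows(X)
  if (config$kernel == "rbf") {
    # share the reduced squared-distance matrix between the bandwidth
    # heuristic and the kernel evaluation
    D2u <- row_sqdist(u$Xu)
    sigma <- if (identical(config$sigma, "median")) {
      median_bw_reduced(D2u, u$counts)
    } else config$sigma
    denom <- if (config$rbf_form == "half_sigma2") 2 * sigma^2 else sigma^2
    Ku <- exp(-D2u / denom)
  } else {
    Ku <- kernel_gram_rows(u$Xu, config, sigma)
  }
  q <- sqrt(u$counts)
  A <- Ku * tcrossprod(q)
  if (center) {
    aq <- as.vector(A %*% q)
    s <- sum(q * aq)
    C <- A - outer(q, aq) / N - outer(aq, q) / N + outer(q, q) * (s / N^2)
  } else {
    C <- A
  }
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  keep <- lam > EIG_FLOOR * max(lam, 0)
  if (!any(keep)) abort("centered kernel has no positive eigenvalues")
  lam <- lam[keep]
  L <- select_num_components(lam, threshold)
  B <- e$vectors[, which(keep)[seq_len(L)], drop = FALSE]
  # map reduced eigenvectors back to per-individual unit eigenvectors
  V <- B[u$idx, , drop = FALSE] / q[u$idx]
  if (center) V <- sweep(V, 2L, colMeans(V))
  # guard round-off: renormalize columns to unit norm
  V <- sweep(V, 2L, sqrt(colSums(V^2)), `/`)
  S <- fix_signs(sweep(V, 2L, sqrt(lam[seq_len(L)]), `*`))
  vf <- lam / sum(lam)
  list(scores = S, eigenvalues = lam, variance_fractions = vf, L = L,
       sigma = sigma, total_available = length(lam))
}

#' Kernel principal component scores from genotypes
#'
#' High-level front end composing the kernel and the eigenproblem: computes
#' the configured kernel (resolving the median-heuristic bandwidth on this
#' dataset when requested), then extracts kernel principal components as in
#' [kpca()]. Exploits duplicated genotype rows for speed; the result is
#' numerically identical to the dense route.
#'
#' @inheritParams linear_kernel
#' @param kernel A [kernel_config()].
#' @param threshold Cumulative-variance threshold in `(0, 1]`.
#' @param center Center the kernel in feature space (default `TRUE`).
#' @return A `component_scores` object; for RBF kernels the resolved
#'   bandwidth is in `attr(, "sigma")`.
#' @export
kpca_scores <- function(geno, kernel = kernel_config(), threshold = 0.8,
                        center = TRUE) {
  X <- geno_matrix(geno)
  fit <- kpca_engine(X, kernel, threshold, center)
  cs <- new_component_scores(
    as.character(geno$iid), fit$scores,
    fit$eigenvalues[seq_len(fit$L)],
    fit$variance_fractions[seq_len(fit$L)],
    total_available = fit$total_available,
    method = "kpca", threshold = threshold
  )
  attr(cs, "sigma") <- fit$sigma
  cs
}

# ---- linear PCA -------------------------------------------------------------

#' Linear principal component scores from genotypes
#'
#' Column-centers the dosage matrix, eigendecomposes the sample covariance
#' matrix (divisor `N`), and projects onto the unit eigenvectors. `L` is
#' chosen by [select_num_components()] over the positive eigenvalues.
#'
#' @inheritParams kpca_scores
#' @return A `component_scores` object.
#' @export
pca_scores <- function(geno, threshold = 0.8) {
  X <- geno_matrix(geno)
  N <- nrow(X)
  if (N < 2L) abort("need at least two individuals")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  C <- crossprod(Xc) / N
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  keep <- lam > EIG_FLOOR * max(lam, 0)
  if (!any(keep)) abort("genotype matrix has no variation after centering")
  lam <- lam[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  L <- select_num_components(lam, threshold)
  V <- vecs[, seq_len(L), drop = FALSE]
  S <- Xc %*% V
  # apply the same deterministic sign rule to scores and loadings jointly
  for (k in seq_len(L)) {
    i <- which.max(abs(S[, k]))
    if (S[i, k] < 0) {
      S[, k] <- -S[, k]
      V[, k] <- -V[, k]
    }
  }
  vf <- lam / sum(lam)
  proj <- list(type = "pca", center = ctr, loadings = V)
  new_component_scores(as.character(geno$iid), unname(S),
                       lam[seq_len(L)], vf[seq_len(L)],
                       total_available = length(lam),
                       method = "pca", threshold = threshold,
                       projector = proj)
}

#' Project new individuals onto fitted components
#'
#' Out-of-sample projection. For PCA, new dosage rows are centered with the
#' training means and multiplied by the loadings. For [kpca()] fits, the new
#' kernel row against the training sample is centered with the training row
#' means and projected on the stored expansion coefficients; `k_new` must
#' then be supplied as the kernel evaluations `k(x_new, x_i)` against the
#' training individuals.
#'
#' @param object A `component_scores` with a stored projector.
#' @param newdata For PCA: a genotype tibble with the training SNP columns.
#'   For KPCA: a numeric matrix of kernel evaluations, one row per new
#'   individual, columns ordered as the training sample.
#' @param ... Unused.
#' @return A numeric matrix of projected scores (columns as in the fit).
#' @export
predict.component_scores <- function(object, newdata, ...) {
  pr <- object$projector
  if (is.null(pr)) {
    abort("this fit does not carry projection information")
  }
  if (pr$type == "pca") {
    Xn <- geno_matrix(newdata)
    S <- sweep(Xn, 2L, pr$center) %*% pr$loadings
    colnames(S) <- colnames(object$scores)
    return(S)
  }
  Kn <- as.matrix(newdata)
  if (ncol(Kn) != length(pr$train_row_means)) {
    abort("kernel evaluations must have one column per training individual")
  }
  if (pr$centered) {
    Kn <- Kn - matrix(pr$train_row_means, nrow(Kn), ncol(Kn), byrow = TRUE) -
      rowMeans(Kn) + pr$train_grand_mean
  }
  S <- Kn %*% pr$alpha
  colnames(S) <- colnames(object$scores)
  S
}
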