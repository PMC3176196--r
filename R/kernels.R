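#' Kernel configuration
#'
#' Describes which genotype-similarity kernel to use and, for the Gaussian
#' radial-basis-function (RBF) kernel, how its bandwidth is set.
#'
#' @param kernel One of `"rbf"` (default), `"linear"`, `"ibs"`.
#' @param sigma RBF bandwidth: a positive number, or `"median"` (default) to
#'   use the median heuristic — the median of all pairwise Euclidean
#'   distances between genotype rows, recomputed on each analyzed dataset.
#' @param rbf_form Exponent convention for the RBF kernel:
#'   `"half_sigma2"` (default), `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`,
#'   the convention under which the median heuristic is usually stated, or
#'   `"sigma2"`, `k(x, y) = exp(-||x - y||^2 / sigma^2)`.
#' @return An object of class `kernel_config`.
#' @export
#' @examples
#' kernel_config("rbf", sigma = "median")
kernel_config <- function(kernel = c("rbf", "linear", "ibs"),
                          sigma = "median",
                          rbf_form = c("half_sigma2", "sigma2")) {
  kernel <- match.arg(kernel)
  rbf_form <- match.arg(rbf_form)
  if (kernel == "rbf") {
    if (!(identical(sigma, "median") ||
          (is.numeric(sigma) && length(sigma) == 1L && sigma > 0))) {
      abort("`sigma` must be a positive number or \"median\"")
    }
  }
  structure(list(kernel = kernel, sigma = sigma, rbf_form = rbf_form),
            class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  cat("<kernel_config> ", x$kernel, sep = "")
  if (x$kernel == "rbf") {
    cat(", sigma = ", if (identical(x$sigma, "median")) "median heuristic"
        else format(x$sigma),
        ", form = ", x$rbf_form, sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- kernel matrices --------------------------------------------------------

new_kernel_matrix <- function(values, kernel_name, params = list()) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1e-300)
  if (asym > 1e-12 * scale) abort("kernel matrix is not symmetric")
  structure(list(values = (values + t(values)) / 2,
                 kernel = kernel_name, params = params),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", x$kernel, ", N = ", nrow(x$values), sep = "")
  if (length(x$params)) {
    cat(" (", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.kernel_matrix <- function(x, ...) x$values

# squared Euclidean distances between rows, via the Gram identity
row_sqdist <- function(X, Y = X) {
  rx <- rowSums(X^2)
  ry <- rowSums(Y^2)
  D2 <- outer(rx, ry, `+`) - 2 * tcrossprod(X, Y)
  D2[D2 < 0] <- 0
  D2
}

#' Linear kernel Gram matrix
#'
#' `K[i, j]` is the dot product of the genotype rows of individuals `i` and
#' `j`. Kernel PCA with this kernel reproduces standard linear PCA.
#'
#' @param geno A genotype tibble (see [read_genotype_tsv()]).
#' @return A `kernel_matrix`.
#' @export
linear_kernel <- function(geno) {
  X <- geno_matrix(geno)
  new_kernel_matrix(tcrossprod(X), "linear")
}

#' Gaussian (RBF) kernel Gram matrix
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))` under the default
#' convention (see [kernel_config()] for the alternative). The diagonal is
#' exactly 1.
#'
#' @inheritParams linear_kernel
#' @param sigma Positive bandwidth, or `"median"` for the median heuristic
#'   ([median_heuristic_bandwidth()]).
#' @param rbf_form Exponent convention, as in [kernel_config()].
#' @return A `kernel_matrix` with `sigma` recorded in `params`.
#' @export
rbf_kernel <- function(geno, sigma = "median",
                       rbf_form = c("half_sigma2", "sigma2")) {
  rbf_form <- match.arg(rbf_form)
  X <- geno_matrix(geno)
  if (identical(sigma, "median")) sigma <- median_heuristic_bandwidth(geno)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("`sigma` must be a single positive number")
  }
  denom <- if (rbf_form == "half_sigma2") 2 * sigma^2 else sigma^2
  K <- exp(-row_sqdist(X) / denom)
  diag(K) <- 1
  new_kernel_matrix(K, "rbf", list(sigma = sigma, rbf_form = rbf_form))
}

#' Identity-by-state (IBS) kernel Gram matrix
#'
#' `K[i, j]` is the mean proportion of alleles shared identical-by-state
#' across the M SNPs: `(1 / (2M)) * sum_m (2 - |g_im - g_jm|)`. Dosages must
#' be integral; fractional (imputed) dosages are rounded with a warning.
#'
#' @inheritParams linear_kernel
#' @return A `kernel_matrix`.
#' @export
ibs_kernel <- function(geno) {
  X <- geno_matrix(geno)
  if (any(X != round(X))) {
    warn("fractional dosages rounded to nearest integer for the IBS kernel")
    X <- round(X)
  }
  D1 <- as.matrix(dist(X, method = "manhattan"))
  K <- 1 - D1 / (2 * ncol(X))
  new_kernel_matrix(unname(K), "ibs")
}

#' Compute a Gram matrix from a kernel configuration
#'
#' @inheritParams linear_kernel
#' @param config A [kernel_config()].
#' @return A `kernel_matrix`.
#' @export
compute_kernel <- function(geno, config = kernel_config()) {
  stopifnot(inherits(config, "kernel_config"))
  switch(config$kernel,
         linear = linear_kernel(geno),
         rbf = rbf_kernel(geno, sigma = config$sigma,
                          rbf_form = config$rbf_form),
         ibs = ibs_kernel(geno))
}

# ---- median heuristic -------------------------------------------------------

#' Median-heuristic RBF bandwidth
#'
#' Returns the median of the `N (N - 1) / 2` pairwise Euclidean distances
#' `||x_i - x_j||`, `i < j`, between genotype rows. If that median is zero
#' (more than half the pairs identical), the mean of the strictly positive
#' distances is returned instead. All rows identical is an error: no finite
#' bandwidth separates the points.
#'
#' Duplicate genotype rows are collapsed and an exact weighted order
#' statistic is taken, so the result is identical to `median(dist(X))` at a
#' fraction of the cost.
#'
#' @inheritParams linear_kernel
#' @return A positive scalar bandwidth.
#' @export
median_heuristic_bandwidth <- function(geno) {
  X <- if (is.matrix(geno)) geno else geno_matrix(geno)
  if (nrow(X) < 2L) abort("need at least two individuals")
  u <- unique_rows(X)
  median_bw_reduced(row_sqdist(u$Xu), u$counts)
}

# median pairwise distance from the squared-distance matrix of the unique
# rows plus multiplicities (zero-distance pairs between duplicated
# individuals included)
median_bw_reduced <- function(d2u, counts) {
  U <- length(counts)
  if (U == 1L) abort("all genotype rows are identical; no pairwise distance is positive")
  ut <- upper.tri(d2u)
  vals <- sqrt(d2u[ut])
  wts <- tcrossprod(counts)[ut]
  n_zero <- sum(counts * (counts - 1) / 2)
  if (n_zero > 0) {
    vals <- c(0, vals)
    wts <- c(n_zero, wts)
  }
  med <- weighted_median_pairs(vals, wts)
  if (med > 0) return(med)
  pos <- vals > 0
  sum(vals[pos] * wts[pos]) / sum(wts[pos])
}

# exact sample median of a weighted multiset, matching stats::median():
# for an even total count, the average of the two middle order statistics.
weighted_median_pairs <- function(vals, wts) {
  o <- order(vals)
  vals <- vals[o]
  cw <- cumsum(wts[o])
  total <- cw[length(cw)]
  kth <- function(k) vals[which(cw >= k)[1L]]
  if (total %% 2 == 1) {
    kth((total + 1) / 2)
  } else {
    (kth(total / 2) + kth(total / 2 + 1)) / 2
  }
}

# collapse duplicate rows; returns unique rows, per-row group index and counts
unique_rows <- function(X) {
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  keep <- !duplicated(key)
  Xu <- X[keep, , drop = FALSE]
  idx <- match(key, key[keep])
  list(Xu = Xu, idx = idx, counts = tabulate(idx, nbins = nrow(Xu)))
}
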