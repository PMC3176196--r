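#' Default 11-SNP region template
#'
#' Minor-allele-frequency targets for the default simulated region: 11 SNPs
#' in three LD blocks of sizes 4, 4 and 3, with common variants spanning the
#' 0.05-0.45 frequency range typical of a tag-SNP panel over a candidate
#' gene.
#'
#' @keywords internal
default_maf_targets <- function() {
  c(0.10, 0.14, 0.22, 0.26,   # block 1
    0.32, 0.30, 0.28, 0.24,   # block 2
    0.18, 0.36, 0.42)         # block 3
}

#' Simulation study configuration
#'
#' Describes one Monte-Carlo study: the LD-structured haplotype pool, the
#' disease model, the sample sizes and the analysis settings. Defaults give
#' an 11-SNP region in three haplotype blocks (sizes 4/4/3) with latent
#' within-block correlation 0.8 and independence across blocks; the 6th SNP
#' is the causal variant and is removed from the analyzed matrix, so the
#' tests must detect it indirectly through LD.
#'
#' @param n_snps Number of SNPs in the region (including the causal one).
#' @param maf_targets Per-SNP minor-allele-frequency targets in `(0, 0.5]`.
#' @param block_sizes Sizes of the LD blocks; must sum to `n_snps`.
#' @param block_correlations Latent pairwise correlation within each block
#'   (recycled to one value per block); across-block correlation is 0.
#' @param causal_index 1-based index of the causal SNP among the `n_snps`.
#' @param relative_risk Multiplicative disease risk per copy of the risk
#'   allele at the causal SNP; `1.0` is the null.
#' @param n_cases,n_controls Per-replicate sample sizes.
#' @param replicates Number of Monte-Carlo replicates.
#' @param alpha_levels Significance levels at which rejections are recorded.
#' @param threshold Cumulative-variance threshold for component selection.
#' @param kernel A [kernel_config()] for the KPCA-LRT arm.
#' @param methods Which tests to run per replicate (`"pca"`, `"kpca"`,
#'   `"single"`).
#' @param pool_size Number of haplotypes in the simulated pool.
#' @param seed Master seed; every random draw in the study derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 11,
                       maf_targets = default_maf_targets(),
                       block_sizes = c(4, 4, 3),
                       block_correlations = 0.8,
                       causal_index = 6,
                       relative_risk = 1.0,
                       n_cases = 500, n_controls = 500,
                       replicates = 1000,
                       alpha_levels = c(0.05, 0.01),
                       threshold = 0.8,
                       kernel = kernel_config(),
                       methods = c("pca", "kpca"),
                       pool_size = 20000,
                       seed = 1) {
  stopifnot(length(maf_targets) == n_snps,
            all(maf_targets > 0), all(maf_targets <= 0.5),
            sum(block_sizes) == n_snps,
            n_cases >= 1, n_controls >= 1,
            threshold > 0, threshold <= 1,
            pool_size >= 2)
  if (replicates < 1) abort("`replicates` must be at least 1")
  if (causal_index < 1 || causal_index > n_snps) {
    abort("`causal_index` must lie in 1..n_snps")
  }
  if (relative_risk < 1) {
    abort("`relative_risk` must be >= 1 (the per-allele risk grid)")
  }
  block_correlations <- rep_len(block_correlations, length(block_sizes))
  for (b in seq_along(block_sizes)) {
    k <- block_sizes[b]
    rho <- block_correlations[b]
    if (rho >= 1 || (k > 1 && rho <= -1 / (k - 1))) {
      abort(sprintf(
        "block %d: correlation %.3f gives a non-positive-definite latent correlation matrix",
        b, rho))
    }
  }
  methods <- match.arg(methods, c("pca", "kpca", "single"), several.ok = TRUE)
  structure(
    list(n_snps = n_snps, maf_targets = maf_targets,
         block_sizes = block_sizes,
         block_correlations = block_correlations,
         causal_index = causal_index, relative_risk = relative_risk,
         n_cases = n_cases, n_controls = n_controls,
         replicates = as.integer(replicates),
         alpha_levels = alpha_levels, threshold = threshold,
         kernel = kernel, methods = methods,
         pool_size = as.integer(pool_size), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_snps, " SNPs, blocks ",
      paste(x$block_sizes, collapse = "/"),
      ", causal #", x$causal_index, ", RR = ", x$relative_risk,
      ", ", x$n_cases, "/", x$n_controls, " cases/controls, ",
      x$replicates, " replicates, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- haplotype pool ---------------------------------------------------------

#' Generate an LD-structured haplotype pool
#'
#' Draws `pool_size` latent multivariate-normal vectors with block-diagonal
#' equicorrelation (within-block correlation from the config, zero across
#' blocks) and dichotomizes column `m` at its upper `maf_targets[m]`
#' quantile, so allele 1 (the minor/risk allele) has frequency close to the
#' target and nearby SNPs in a block are in LD. Deterministic given the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for the pool draw; defaults to `cfg$seed`.
#' @return A `haplotype_pool`: list with `haplotypes` (pool_size x n_snps
#'   0/1 integer matrix), `maf_targets`, `block_assignment` and `seed`.
#' @export
make_haplotype_pool <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- as.integer(seed)  # force before saving the ambient RNG state
  blocks <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  P <- cfg$pool_size
  H <- matrix(0L, P, cfg$n_snps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_along(cfg$block_sizes)) {
    idx <- which(blocks == b)
    k <- length(idx)
    R <- matrix(cfg$block_correlations[b], k, k)
    diag(R) <- 1
    Rchol <- tryCatch(chol(R), error = function(e) {
      abort(sprintf("block %d: latent correlation matrix is not positive definite", b))
    })
    Z <- matrix(rnorm(P * k), P, k) %*% Rchol
    for (j in seq_len(k)) {
      H[, idx[j]] <- as.integer(Z[, j] > qnorm(1 - cfg$maf_targets[idx[j]]))
    }
  }
  colnames(H) <- sprintf("snp%02d", seq_len(cfg$n_snps))
  structure(list(haplotypes = H, maf_targets = cfg$maf_targets,
                 block_assignment = blocks, seed = seed),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " SNPs, ",
      length(unique(x$block_assignment)), " blocks, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# save/restore the global RNG state so generator functions are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- case-control sampling --------------------------------------------------

#' Sample a case-control dataset from a haplotype pool
#'
#' Individuals are formed by drawing two haplotypes with replacement
#' (Hardy-Weinberg pairing). Controls are drawn uniformly from the pool.
#' Cases are drawn under the rare-disease multiplicative model: disease risk
#' is proportional to `RR^g` where `g` is the risk-allele count at the
#' causal SNP, which factorizes over haplotypes, so each case haplotype is
#' drawn with weight `RR` when it carries the risk allele and `1` otherwise.
#' The causal SNP column is then removed from the returned matrix, so any
#' association is indirect, through LD with the remaining markers.
#'
#' @param pool A `haplotype_pool`.
#' @param cfg A [sim_config()] (supplies sample sizes, causal index and RR).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return A simulated dataset tibble: `iid`, `status`, then the `n_snps - 1`
#'   non-causal SNP dosage columns.
#' @export
sample_case_control <- function(pool, cfg, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(cfg, "sim_config"))
  if (cfg$relative_risk < 1) abort("`relative_risk` must be >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  H <- pool$haplotypes
  P <- nrow(H)
  nca <- cfg$n_cases
  nco <- cfg$n_controls
  risk_allele <- H[, cfg$causal_index] == 1L
  w <- ifelse(risk_allele, cfg$relative_risk, 1)
  case_idx <- sample.int(P, 2 * nca, replace = TRUE, prob = w)
  ctrl_idx <- sample.int(P, 2 * nco, replace = TRUE)
  G_cases <- H[case_idx[seq_len(nca)], , drop = FALSE] +
    H[case_idx[nca + seq_len(nca)], , drop = FALSE]
  G_ctrls <- H[ctrl_idx[seq_len(nco)], , drop = FALSE] +
    H[ctrl_idx[nco + seq_len(nco)], , drop = FALSE]
  G <- rbind(G_cases, G_ctrls)[, -cfg$causal_index, drop = FALSE]
  dplyr::bind_cols(
    tibble(iid = c(sprintf("case%04d", seq_len(nca)),
                   sprintf("ctrl%04d", seq_len(nco))),
           status = rep(c(1L, 0L), c(nca, nco))),
    as_tibble(G)
  )
}

# ---- study runner -----------------------------------------------------------

#' Run a replicated type-I-error / power study
#'
#' Builds the haplotype pool, then for each replicate samples a case-control
#' dataset, runs the configured tests, and records the p-values. Rejection
#' proportions at each significance level are computed over the replicates
#' whose fit converged. Per-replicate seeds are drawn up front from the
#' master seed, so the study is a pure function of its configuration and any
#' single replicate can be reproduced in isolation.
#'
#' @param cfg A [sim_config()].
#' @param progress Emit a message every 100 replicates (default `FALSE`).
#' @return A `study_result` with elements `rates` (tibble: method, alpha,
#'   n_used, rejections, rate), `replicates` (tibble of per-replicate
#'   p-values, `L` and seeds), `non_converged` (per-method counts), `mean_L`
#'   and `config`.
#' @export
run_study <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  pool <- make_haplotype_pool(cfg, seed = sample.int(.Machine$integer.max, 1L))
  rep_seeds <- sample.int(.Machine$integer.max, cfg$replicates)
  run_one <- function(r) {
    set.seed(rep_seeds[r])
    dat <- sample_case_control(pool, cfg)
    out <- list()
    if ("pca" %in% cfg$methods) {
      t <- pca_lrt(dat, threshold = cfg$threshold)
      out$pca_lrt <- tibble(replicate = r, seed = rep_seeds[r],
                            method = "pca_lrt", p_value = t$p_value,
                            L = t$L, converged = t$converged)
    }
    if ("kpca" %in% cfg$methods) {
      t <- kpca_lrt(dat, kernel = cfg$kernel, threshold = cfg$threshold)
      out$kpca_lrt <- tibble(replicate = r, seed = rep_seeds[r],
                             method = "kpca_lrt", p_value = t$p_value,
                             L = t$L, converged = t$converged)
    }
    if ("single" %in% cfg$methods) {
      t <- single_locus_test(dat)
      out$single <- tibble(replicate = r, seed = rep_seeds[r],
                           method = "single_locus", p_value = t$p_value,
                           L = NA_integer_, converged = t$converged)
    }
    dplyr::bind_rows(out)
  }
  reps <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    reps[[r]] <- run_one(r)
    if (progress && r %% 100 == 0) {
      inform(sprintf("replicate %d / %d", r, cfg$replicates))
    }
  }
  reps <- dplyr::bind_rows(reps)
  usable <- dplyr::filter(reps, .data$converged, !is.na(.data$p_value))
  rates <- tidyr::crossing(method = unique(reps$method),
                           alpha = cfg$alpha_levels) |>
    dplyr::left_join(usable, by = "method", relationship = "many-to-many") |>
    dplyr::group_by(.data$method, .data$alpha) |>
    dplyr::summarise(
      n_used = sum(!is.na(.data$p_value)),
      rejections = sum(.data$p_value <= .data$alpha, na.rm = TRUE),
      rate = .data$rejections / .data$n_used,
      .groups = "drop"
    )
  non_conv <- reps |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(non_converged = sum(!.data$converged), .groups = "drop")
  mean_L <- usable |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_L = mean(.data$L), .groups = "drop")
  structure(list(rates = rates, replicates = reps,
                 non_converged = non_conv, mean_L = mean_L,
                 config = cfg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cfg <- x$config
  cat("<study_result> RR = ", cfg$relative_risk, ", ",
      cfg$n_cases, "/", cfg$n_controls, " cases/controls, ",
      cfg$replicates, " replicates\n", sep = "")
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.study_result <- function(x, ...) x$rates

#' @export
glance.study_result <- function(x, ...) {
  cfg <- x$config
  tibble(relative_risk = cfg$relative_risk,
         n_cases = cfg$n_cases, n_controls = cfg$n_controls,
         replicates = cfg$replicates, seed = cfg$seed,
         non_converged = sum(x$non_converged$non_converged))
}

#' Write a study result to disk
#'
#' Emits `rates.tsv` (one row per method and significance level),
#' `result.json` (rates plus convergence bookkeeping) and, optionally,
#' `pvalues.tsv` with the per-replicate p-values for calibration plots.
#'
#' @param x A `study_result`.
#' @param dir Output directory (created if needed).
#' @param pvalues Also write the per-replicate p-value dump.
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(x, dir, pvalues = FALSE) {
  stopifnot(inherits(x, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$rates, file.path(dir, "rates.tsv"))
  cfg <- x$config
  jsonlite::write_json(
    list(rates = x$rates, non_converged = x$non_converged,
         mean_L = x$mean_L,
         config = list(n_snps = cfg$n_snps, causal_index = cfg$causal_index,
                       relative_risk = cfg$relative_risk,
                       n_cases = cfg$n_cases, n_controls = cfg$n_controls,
                       replicates = cfg$replicates, seed = cfg$seed,
                       threshold = cfg$threshold,
                       kernel = cfg$kernel$kernel)),
    file.path(dir, "result.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  if (pvalues) {
    readr::write_tsv(x$replicates, file.path(dir, "pvalues.tsv"))
  }
  invisible(dir)
}
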