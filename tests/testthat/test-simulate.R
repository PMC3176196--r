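small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 60, n_controls = 60, replicates = 3,
         pool_size = 4000, seed = 5),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration validation catches inconsistent studies", {
  expect_error(sim_config(causal_index = 12), "causal_index")
  expect_error(sim_config(relative_risk = 0.8), "relative_risk")
  expect_error(sim_config(replicates = 0), "replicates")
  expect_error(sim_config(block_correlations = 1.0), "positive-definite")
  expect_error(sim_config(block_correlations = -0.5), "positive-definite")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("haplotype pools hit their MAF targets and are reproducible", {
  cfg <- small_cfg(pool_size = 20000)
  pool <- make_haplotype_pool(cfg)
  freq <- colMeans(pool$haplotypes)
  expect_true(all(abs(freq - cfg$maf_targets) < 0.03))
  expect_true(all(freq > 0 & freq < 1))  # both alleles present everywhere

  pool2 <- make_haplotype_pool(cfg)
  expect_identical(pool$haplotypes, pool2$haplotypes)
})

test_that("zero latent correlation gives negligible allele correlation", {
  cfg <- sim_config(block_correlations = 0, pool_size = 50000, seed = 17,
                    replicates = 1)
  pool <- make_haplotype_pool(cfg)
  r2 <- cor(pool$haplotypes)^2
  expect_lt(max(r2[upper.tri(r2)]), 0.01)
})

test_that("realized LD matches bivariate-normal orthant probabilities", {
  cfg <- sim_config(n_snps = 2, maf_targets = c(0.3, 0.3),
                    block_sizes = 2, block_correlations = 0.9,
                    causal_index = 1, pool_size = 50000, seed = 23,
                    replicates = 1)
  pool <- make_haplotype_pool(cfg)
  t <- qnorm(1 - 0.3)
  p11 <- oracle_orthant_prob(t, 0.9)
  r_expect <- (p11 - 0.3^2) / (0.3 * 0.7)
  r_real <- cor(pool$haplotypes[, 1], pool$haplotypes[, 2])
  expect_lt(abs(r_real - r_expect), 0.02)
})

test_that("case-control sampling removes the causal SNP and codes additively", {
  cfg <- small_cfg(relative_risk = 1.5)
  pool <- make_haplotype_pool(cfg)
  dat <- sample_case_control(pool, cfg, seed = 9)
  expect_equal(nrow(dat), 120)
  expect_equal(setdiff(names(dat), c("iid", "status")),
               sprintf("snp%02d", setdiff(1:11, 6)))
  X <- as.matrix(dat[-(1:2)])
  expect_true(all(X %in% 0:2))
  expect_equal(sum(dat$status), 60)
})

test_that("an extreme relative risk loads cases with risk alleles", {
  cfg <- sim_config(n_cases = 200, n_controls = 200, replicates = 1,
                    relative_risk = 1e6, causal_index = 6,
                    pool_size = 20000, seed = 31)
  pool <- make_haplotype_pool(cfg)
  # look at the causal column before removal by resampling haplotypes directly
  w <- ifelse(pool$haplotypes[, 6] == 1L, cfg$relative_risk, 1)
  withr::with_seed(32, {
    idx <- sample.int(nrow(pool$haplotypes), 400, TRUE, prob = w)
    gcausal <- pool$haplotypes[idx[1:200], 6] + pool$haplotypes[idx[201:400], 6]
  })
  expect_gt(mean(gcausal >= 1), 0.999)
})

test_that("under the null, case and control dosage distributions agree", {
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, replicates = 1,
                    pool_size = 20000, seed = 41)
  pool <- make_haplotype_pool(cfg)
  dat <- sample_case_control(pool, cfg, seed = 42)
  X <- as.matrix(dat[-(1:2)])
  diff <- colMeans(X[dat$status == 1, ]) - colMeans(X[dat$status == 0, ])
  # mean dosage difference ~ N(0, ~2pq(1/n1+1/n2)); 4 SEs at n = 2000
  se <- sqrt(2 * 0.5 * 0.5 * (1 / 2000 + 1 / 2000))
  expect_lt(max(abs(diff)), 4 * se)
})

test_that("a study is a pure function of its configuration", {
  cfg <- small_cfg()
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1$rates, s2$rates)
  expect_identical(s1$replicates, s2$replicates)
  expect_equal(nrow(s1$replicates), 2 * cfg$replicates)  # two methods
  expect_true(all(s1$rates$rate >= 0 & s1$rates$rate <= 1))

  # a single replicate is reproducible in isolation from its logged seed
  r2 <- s1$replicates[s1$replicates$replicate == 2 &
                        s1$replicates$method == "pca_lrt", ]
  pool <- make_haplotype_pool(cfg, seed = withr::with_seed(cfg$seed, {
    sample.int(.Machine$integer.max, 1)
  }))
  dat <- sample_case_control(pool, cfg, seed = r2$seed)
  expect_equal(pca_lrt(dat, threshold = cfg$threshold)$p_value, r2$p_value)
})

test_that("permuting pool SNP order leaves study decisions unchanged", {
  cfg <- small_cfg(methods = "pca")
  s1 <- run_study(cfg)
  # permute non-causal SNPs in the pool, rerun the analysis stream manually
  pool <- make_haplotype_pool(cfg, seed = withr::with_seed(cfg$seed, {
    sample.int(.Machine$integer.max, 1)
  }))
  seeds <- withr::with_seed(cfg$seed, {
    sample.int(.Machine$integer.max, 1)  # pool seed draw
    sample.int(.Machine$integer.max, cfg$replicates)
  })
  p_orig <- p_perm <- numeric(cfg$replicates)
  perm <- withr::with_seed(99, sample(10))
  for (r in seq_len(cfg$replicates)) {
    dat <- sample_case_control(pool, cfg, seed = seeds[r])
    p_orig[r] <- pca_lrt(dat, threshold = cfg$threshold)$p_value
    datp <- dat[c(1, 2, 2 + perm)]
    p_perm[r] <- pca_lrt(datp, threshold = cfg$threshold)$p_value
  }
  expect_equal(p_orig, p_perm, tolerance = 1e-9)
  expect_equal(sort(s1$replicates$p_value), sort(p_orig), tolerance = 1e-12)
})

test_that("study results serialize to TSV and JSON", {
  cfg <- small_cfg()
  s <- run_study(cfg)
  out <- withr::local_tempdir()
  write_study_result(s, out, pvalues = TRUE)
  expect_true(file.exists(file.path(out, "rates.tsv")))
  expect_true(file.exists(file.path(out, "result.json")))
  expect_true(file.exists(file.path(out, "pvalues.tsv")))
  rt <- readr::read_tsv(file.path(out, "rates.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(rt), nrow(s$rates))
  js <- jsonlite::read_json(file.path(out, "result.json"))
  expect_equal(js$config$seed, cfg$seed)
})
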