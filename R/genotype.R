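#' Genotype tables
#'
#' Throughout the package a genotype table is an ordinary data frame (usually
#' a tibble) whose first column, `iid`, holds individual identifiers and whose
#' remaining columns hold additively coded SNP dosages: the count of coded
#' alleles, so `0`, `1` or `2` (fractional values are permitted after mean
#' imputation of missing genotypes). A phenotype table has columns `iid` and
#' `status` with `status` coded `1` for cases and `0` for controls. A
#' simulated dataset carries both: `iid`, `status`, then the SNP columns.
#'
#' @name genotype-tables
#' @keywords internal
NULL

# ---- internal validation helpers -------------------------------------------

# Extract the numeric dosage matrix (individuals x SNPs) from a genotype
# table, with iid rownames. Non-dosage bookkeeping columns (iid, status) are
# dropped.
geno_matrix <- function(geno) {
  stopifnot(is.data.frame(geno))
  if (!"iid" %in% names(geno)) {
    abort("genotype table must have an `iid` column")
  }
  snp_cols <- setdiff(names(geno), c("iid", "status"))
  if (length(snp_cols) < 1L) {
    abort("genotype table has no SNP columns")
  }
  X <- as.matrix(geno[snp_cols])
  if (!is.numeric(X)) abort("SNP columns must be numeric dosages")
  rownames(X) <- as.character(geno$iid)
  X
}

validate_genotypes <- function(geno, require_complete = TRUE) {
  X <- geno_matrix(geno)
  if (anyDuplicated(rownames(X))) abort("duplicated individual ids")
  if (require_complete && anyNA(X)) abort("genotype table contains NA dosages")
  rng <- range(X, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("genotype dosages must lie in [0, 2]")
  }
  invisible(geno)
}

validate_phenotypes <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  if (!all(c("iid", "status") %in% names(pheno))) {
    abort("phenotype table must have columns `iid` and `status`")
  }
  s <- pheno$status
  if (anyNA(s) || !all(s %in% c(0, 1))) {
    abort("`status` must be 0 (control) or 1 (case) with no missing values")
  }
  if (sum(s == 1) < 1 || sum(s == 0) < 1) {
    abort("phenotype must contain at least one case and one control")
  }
  invisible(pheno)
}

# Align a phenotype table to the row order of a genotype table; errors name
# the first few offending ids on any mismatch.
align_phenotype <- function(geno, pheno) {
  validate_phenotypes(pheno)
  ids <- as.character(geno$iid)
  midx <- match(ids, as.character(pheno$iid))
  if (anyNA(midx)) {
    bad <- head(ids[is.na(midx)], 5L)
    abort(paste0(
      "individuals missing from phenotype table: ",
      paste(bad, collapse = ", ")
    ))
  }
  as.integer(pheno$status[midx])
}

# Resolve (geno, pheno) into a list(X, y): pheno may be NULL when the
# genotype table itself carries a `status` column (as simulated data does).
resolve_data <- function(geno, pheno = NULL) {
  validate_genotypes(geno)
  if (is.null(pheno)) {
    if (!"status" %in% names(geno)) {
      abort("no phenotype given and genotype table has no `status` column")
    }
    pheno <- tibble(iid = geno$iid, status = geno$status)
  }
  y <- align_phenotype(geno, pheno)
  list(X = geno_matrix(geno), y = y)
}

# ---- readers ----------------------------------------------------------------

#' Read an additively coded genotype matrix from a TSV file
#'
#' The file must have a header line `IID<TAB>snp1<TAB>...` followed by one row
#' per individual with dosages in `{0, 1, 2}` or `NA`. Missing dosages are
#' replaced by the per-SNP mean of the observed dosages; the number of imputed
#' entries is recorded in the `"n_imputed"` attribute.
#'
#' @param path Path to a tab-separated genotype file.
#' @return A genotype tibble (`iid` + one numeric column per SNP).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("IID\tsnpA\tsnpB", "s1\t0\t2", "s2\t1\tNA"), tf)
#' g <- read_genotype_tsv(tf)
#' attr(g, "n_imputed")
read_genotype_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort("genotype file needs a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  m <- length(hdr) - 1L
  if (m < 1L) abort("genotype header names no SNPs")
  rows <- fields[-1L]
  bad <- which(lengths(rows) != m + 1L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d has %d fields, expected %d",
                  bad[1L] + 1L, lengths(rows)[bad[1L]], m + 1L))
  }
  iid <- vapply(rows, `[[`, character(1), 1L)
  X <- matrix(NA_real_, nrow = length(rows), ncol = m)
  for (i in seq_along(rows)) {
    X[i, ] <- suppressWarnings(as.numeric(rows[[i]][-1L]))
  }
  colnames(X) <- hdr[-1L]
  observed_ok <- X[!is.na(X)] %in% c(0, 1, 2)
  if (!all(observed_ok)) abort("genotype dosages must be 0, 1, 2 or NA")
  out <- impute_column_means(X)
  g <- tibble(iid = iid)
  g <- dplyr::bind_cols(g, as_tibble(out$X))
  attr(g, "n_imputed") <- out$n_imputed
  g
}

#' Read a case-control phenotype file
#'
#' Expects a header `IID<TAB>status` and one row per individual with status
#' `0` (control) or `1` (case).
#'
#' @param path Path to a tab-separated phenotype file.
#' @return A tibble with columns `iid` and `status`.
#' @export
read_phenotype_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (ncol(tb) != 2L) abort("phenotype file must have exactly two columns")
  names(tb) <- c("iid", "status")
  tb$status <- suppressWarnings(as.integer(tb$status))
  validate_phenotypes(tb)
  tb
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Each biallelic SNP record contributes one column of ALT-allele counts
#' (0/1/2) computed from the `GT` field; phased and unphased genotypes are
#' both accepted. Multiallelic records are skipped with a warning. Missing
#' genotypes are mean-imputed per SNP.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param region Optional region string `"chrom:start-end"` (1-based,
#'   inclusive on both ends); only records inside it are kept.
#' @return A genotype tibble (`iid` + one column per SNP, named by the VCF ID
#'   field where present, else `chrom_pos`).
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(as.matrix(fx))  # single-record VCF
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort("VCF contains no records")
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    rg <- parse_region(region)
    pos <- as.numeric(fix$POS)
    keep <- fix$CHROM == rg$chrom & pos >= rg$start & pos <= rg$end
    if (!any(keep)) {
      abort(sprintf("no VCF records in region %s", region))
    }
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi & keep)) {
    warn(sprintf("skipping %d multiallelic record(s)", sum(multi & keep)))
  }
  keep <- keep & !multi
  if (!any(keep)) abort("no biallelic records to read")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  fallback <- paste(fix$CHROM, fix$POS, sep = "_")
  ids[is.na(ids) | ids == "."] <- fallback[is.na(ids) | ids == "."]
  # ALT-allele count: number of "1" alleles in the GT string
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  X <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), ids))
  for (i in seq_len(nrow(gt))) {
    X[, i] <- vapply(gt[i, ], count_alt, numeric(1))
  }
  out <- impute_column_means(X)
  g <- tibble(iid = colnames(gt))
  g <- dplyr::bind_cols(g, as_tibble(out$X))
  attr(g, "n_imputed") <- out$n_imputed
  g
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) abort("region must look like \"chrom:start-end\"")
  list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
}

impute_column_means <- function(X) {
  n_imp <- 0L
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (all(miss)) {
      abort(sprintf("SNP %s has no observed genotypes", colnames(X)[j]))
    }
    if (any(miss)) {
      X[miss, j] <- mean(X[!miss, j])
      n_imp <- n_imp + sum(miss)
    }
  }
  list(X = X, n_imputed = n_imp)
}

# ---- QC ---------------------------------------------------------------------

#' Filter SNP columns on minor allele frequency
#'
#' Drops monomorphic SNPs (constant dosage) and SNPs whose sample minor allele
#' frequency, computed on the pooled sample, is below `maf_min`. Column order
#' is otherwise preserved. Dropped SNP names are recorded in the
#' `"dropped_snps"` attribute and reported via a message.
#'
#' @param geno A genotype tibble.
#' @param maf_min Minimum sample MAF in `[0, 0.5)`; the default `0` drops only
#'   monomorphic SNPs.
#' @return The filtered genotype tibble.
#' @export
qc_filter <- function(geno, maf_min = 0) {
  stopifnot(is.numeric(maf_min), length(maf_min) == 1L,
            maf_min >= 0, maf_min < 0.5)
  validate_genotypes(geno)
  X <- geno_matrix(geno)
  p <- colMeans(X) / 2          # coded-allele frequency
  maf <- pmin(p, 1 - p)
  mono <- apply(X, 2L, function(v) all(v == v[1L]))
  keep <- !mono & maf >= maf_min
  if (!any(keep)) abort("no SNPs survive QC filtering")
  dropped <- colnames(X)[!keep]
  if (length(dropped) > 0L) {
    inform(paste0("qc_filter dropped ", length(dropped), " SNP(s): ",
                  paste(dropped, collapse = ", ")))
  }
  out <- geno[c(intersect(c("iid", "status"), names(geno)), colnames(X)[keep])]
  attr(out, "dropped_snps") <- dropped
  as_tibble(out)
}

#' Write a genotype tibble as TSV
#'
#' Inverse of [read_genotype_tsv()] for complete (non-imputed) data.
#'
#' @param geno A genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(geno, path) {
  X <- geno_matrix(geno)
  hdr <- paste(c("IID", colnames(X)), collapse = "\t")
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], format(X[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
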