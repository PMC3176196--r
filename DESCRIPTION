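Package: kpcatest
Title: Gene-Based Case-Control Association Testing via Kernel Principal
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region- and gene-based tests of association between a set of
    single-nucleotide polymorphisms (SNPs) and a binary disease phenotype.
    Kernel principal component analysis (KPCA) extracts nonlinear principal
    components from an additively coded genotype matrix; the retained
    components are tested jointly against case-control status with a
    logistic-regression likelihood-ratio test (KPCA-LRT). Linear PCA-LRT
    and a single-locus test are provided as comparators, together with a
    haplotype-pool simulator for assessing type-I error and power under an
    LD-structured region with a per-allele relative-risk disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
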