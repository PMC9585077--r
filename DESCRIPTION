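Package: snpArrayEval
Title: Imputation-Based Coverage and Polygenic-Score Benchmarking of SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks genotyping SNP arrays by mask-and-impute cross-validation
    against phased whole-genome panels. Simulates LD-structured haplotype panels,
    array manifests and GWAS summary statistics; extracts pseudo-array genotypes
    at manifest positions under stratified tenfold cross-validation; imputes
    masked sites with a diploid Li-Stephens haplotype-copying hidden Markov
    model; and scores performance by SNP-wise imputation r-squared, MAF-binned
    imputation coverage, pruning-and-thresholding polygenic scores, polygenic
    score correlation and absolute difference of percentile ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
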