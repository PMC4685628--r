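Package: mdrscan
Title: Case-Control Epistasis Screening by Multifactor-Dimensionality Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide epistasis screening in
    case-control genotype data: quality control (missingness,
    heterozygosity, duplicates, genotype PCA, minor-allele frequency and
    Hardy-Weinberg filters), greedy tag-SNP reduction by linkage
    disequilibrium r-squared, single-SNP association with odds ratios and
    Benjamini-Hochberg correction, and an exhaustive pairwise
    multifactor-dimensionality reduction (MDR) scan scored by 10-fold
    cross-validated balanced accuracy with permutation-based significance.
    Includes a synthetic cohort generator with planted two-locus epistatic
    effects so every stage can be verified against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
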