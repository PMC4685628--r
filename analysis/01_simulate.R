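#!/usr/bin/env Rscript
# Stage 1 — synthetic cohorts.
#
# Builds the two case-control cohorts the screen is shaped around:
#   cohort A: 49 cases vs 109 controls (the sporadic-MTC shape)
#   cohort B: 38 cases vs 111 controls (the juvenile-PTC shape)
# each with 1,000 biallelic SNPs in 10-SNP LD blocks (target adjacent
# r2 0.8), 2% MCAR missingness, sex/age covariates, and one planted
# epistatic pair per cohort: an xor (checkerboard) model in A and a
# jointly-dominant threshold model in B. Truth records are written next
# to the data so later stages can be judged against what was planted.

suppressPackageStartupMessages(library(mdrscan))

out <- "results/analysis/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohorts <- list(
  cohortA = sim_config(
    n_cases = 49, n_controls = 109, n_snps = 1000, block_size = 10,
    within_block_r2 = 0.8, missing_rate = 0.02,
    planted = list(list(
      snp1 = 251L, snp2 = 741L,
      model = make_penetrance_model("xor", 0.05, 0.45, 0.3, 0.3,
                                    label = "planted xor"))),
    seed = 101L),
  cohortB = sim_config(
    n_cases = 38, n_controls = 111, n_snps = 1000, block_size = 10,
    within_block_r2 = 0.8, missing_rate = 0.02,
    planted = list(list(
      snp1 = 301L, snp2 = 671L,
      model = make_penetrance_model("threshold", 0.05, 0.4, 0.3, 0.3,
                                    label = "planted threshold"))),
    seed = 202L))

for (nm in names(cohorts)) {
  sim <- simulate_cohort(cohorts[[nm]])
  prefix <- file.path(out, nm)
  write_dataset(sim$dataset, prefix)
  write_plink_text(sim$dataset, prefix)
  write_truth_record(sim$truth, paste0(prefix, ".truth.tsv"))
  message(nm, ": ", nrow(sim$dataset$genotypes), " samples x ",
          ncol(sim$dataset$genotypes), " SNPs; planted pair ",
          sim$truth$planted[[1]]$id1, " x ", sim$truth$planted[[1]]$id2,
          " (", sim$truth$planted[[1]]$model$kind, ")")
}
message("wrote ", out)
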