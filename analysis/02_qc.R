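#!/usr/bin/env Rscript
# Stage 2 — quality control.
#
# Applies the full QC cascade to each simulated cohort with the standard
# thresholds (sample missingness >7%, heterozygosity beyond +/-2 SD,
# duplicate pairs at mean IBS >= 0.95, 6-SD PCA ancestry outliers;
# variant missingness >5%, MAF < 1%, HWE exact p < 1e-5 in controls) and
# writes per-sample/per-variant reports. On clean synthetic cohorts the
# removals come almost entirely from the heterozygosity tails and the
# MAF filter at the low end of the simulated MAF range.

suppressPackageStartupMessages(library(mdrscan))

sim_dir <- "results/analysis/sim"
out <- "results/analysis/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (nm in c("cohortA", "cohortB")) {
  ds <- read_dataset(file.path(sim_dir, nm))
  res <- apply_qc(ds, qc_thresholds())
  print(res$report)
  write_qc_report(res$report, file.path(out, nm))
  write_dataset(res$dataset, file.path(out, nm))
}
message("wrote ", out)
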