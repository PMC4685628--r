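# End-to-end orchestration: simulate or load genotypes, run QC, tag-SNP
# reduction, single-SNP association and the pairwise MDR scan, and render
# tables in the shape used to report gene-gene interaction screens
# (interaction table: SNP1, SNP2, gene1, gene2, CVV; SNP table:
# frequencies, OR [95% CI], nominal and adjusted p).

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to generate the cohort, or `NULL` to load
#'   from files.
#' @param input_prefix when `sim` is `NULL`: prefix for
#'   [read_dataset()].
#' @param annotation optional path to a gene annotation
#'   ([read_gene_annotation()]).
#' @param qc a [qc_thresholds()].
#' @param r2_threshold,window_bp tag-SNP selection parameters.
#' @param mdr an [mdr_config()].
#' @param gene_mapped_only restrict the MDR pair universe to gene-mapped
#'   tag SNPs (the screen's convention); `FALSE` scans all tag pairs.
#' @param workers parallel workers for the scan.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, input_prefix = NULL,
                            annotation = NULL, qc = qc_thresholds(),
                            r2_threshold = 0.8, window_bp = 250000,
                            mdr = mdr_config(), gene_mapped_only = TRUE,
                            workers = 1L) {
  if (is.null(sim) && is.null(input_prefix))
    stop("either sim or input_prefix must be given")
  structure(list(sim = sim, input_prefix = input_prefix,
                 annotation = annotation, qc = qc,
                 r2_threshold = r2_threshold, window_bp = window_bp,
                 mdr = mdr, gene_mapped_only = gene_mapped_only,
                 workers = as.integer(workers)),
            class = "pipeline_config")
}

#' Run the full epistasis screen
#'
#' simulate/load -> QC -> tag-SNP selection -> single-SNP association
#' (on tag SNPs) -> exhaustive pairwise MDR. Fully deterministic under
#' the seeds in the configuration. Stage timings go to `message()`
#' (stderr); nothing is written unless `out_dir` is given, in which case
#' the stage tables land there as TSVs with stable content (no
#' timestamps), so identical configurations yield byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage tables.
#' @return a `pipeline_run`: list with `config`, `truth` (when
#'   simulated), `qc_report`, `dataset` (post-QC), `tags`, `association`,
#'   `mdr` (ranked pairs), `significant`, `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  truth <- NULL
  ds <- stage("load", {
    if (!is.null(config$sim)) {
      simres <- simulate_cohort(config$sim)
      truth <- simres$truth
      simres$dataset
    } else read_dataset(config$input_prefix)
  })
  if (!is.null(config$annotation))
    ds <- stage("annotate",
                annotate_genes(ds, read_gene_annotation(config$annotation)))
  qc <- stage("qc", apply_qc(ds, config$qc))
  tags <- stage("tag", greedy_tag_selection(qc$dataset, config$r2_threshold,
                                            config$window_bp))
  tag_ds <- subset_dataset(qc$dataset, variants = tags$tags)
  assoc <- stage("assoc", single_snp_association(tag_ds))
  pairs <- stage("pairs", pair_universe(
    qc$dataset, tags = tags, gene_mapped = config$gene_mapped_only))
  mdr <- stage("mdr", scan_pairs(qc$dataset, pairs, config$mdr,
                                 config$workers))
  run <- structure(list(config = config, truth = truth,
                        qc_report = qc$report, dataset = qc$dataset,
                        tags = tags, association = assoc, mdr = mdr,
                        significant = significance_filter(
                          mdr, config$mdr$cvv_threshold),
                        version = as.character(
                          utils::packageVersion("mdrscan"))),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:\n")
  print(x$qc_report)
  cat(sprintf("  %d tag SNPs; %d pairs scanned; %d significant (CVV > %g)\n",
              length(x$tags$tags), nrow(x$mdr), nrow(x$significant),
              x$config$mdr$cvv_threshold))
  invisible(x)
}

#' Render the gene-gene interaction table
#'
#' Column order `SNP1, SNP2, gene1, gene2, CVV` with CVV printed to three
#' decimals; unannotated SNPs get `NA` genes.
#'
#' @param models ranked data.frame from [scan_pairs()].
#' @return data.frame of character columns ready for TSV.
#' @export
render_interaction_table <- function(models) {
  data.frame(SNP1 = models$id1, SNP2 = models$id2,
             gene1 = ifelse(is.na(models$gene1), "NA", models$gene1),
             gene2 = ifelse(is.na(models$gene2), "NA", models$gene2),
             CVV = sprintf("%.3f", models$cvv),
             stringsAsFactors = FALSE)
}

#' Render the per-SNP association table
#'
#' Columns `SNP, gene, freq_cases, freq_controls, OR_95CI, p, p_adjusted`
#' with the OR and its Woolf interval formatted as `OR [lo-hi]`.
#'
#' @param assoc data.frame from [single_snp_association()].
#' @param snps optional ids to keep (errors on ids absent from `assoc`).
#' @return data.frame of character columns ready for TSV.
#' @export
render_snp_table <- function(assoc, snps = NULL) {
  if (!is.null(snps)) {
    missing_ids <- setdiff(snps, assoc$id)
    if (length(missing_ids))
      stop("SNP absent from association results: ", missing_ids[1L])
    assoc <- assoc[match(snps, assoc$id), , drop = FALSE]
  }
  fmt_ci <- function(or, lo, hi)
    ifelse(is.na(lo), sprintf("%.4g [NA]", or),
           sprintf("%.4g [%.4g-%.4g]", or, lo, hi))
  data.frame(SNP = assoc$id,
             gene = ifelse(is.na(assoc$gene), "NA", assoc$gene),
             freq_cases = sprintf("%.4g", assoc$freq_cases),
             freq_controls = sprintf("%.4g", assoc$freq_controls),
             OR_95CI = fmt_ci(assoc$or, assoc$ci_lo, assoc$ci_hi),
             p = sprintf("%.4g", assoc$p_nominal),
             p_adjusted = sprintf("%.4g", assoc$p_adjusted),
             stringsAsFactors = FALSE)
}

#' Write every stage table of a run
#'
#' Emits `qc_samples.tsv`, `qc_variants.tsv`, `qc_summary.txt`,
#' `tags.tsv`, `association.tsv`, `interactions.tsv`,
#' `interactions_significant.tsv` and, for simulated runs, `truth.tsv`.
#' Content depends only on the run (no timestamps), so re-running an
#' identical configuration reproduces the files byte for byte.
#'
#' @param run a `pipeline_run`.
#' @param out_dir directory (created if needed).
#' @export
write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_qc_report(run$qc_report, p("run"))
  write_tag_set(run$tags, p("tags.tsv"))
  data.table::fwrite(render_snp_table(run$association), p("association.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(render_interaction_table(run$mdr),
                     p("interactions.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(render_interaction_table(run$significant),
                     p("interactions_significant.tsv"), sep = "\t",
                     quote = FALSE)
  if (!is.null(run$truth)) write_truth_record(run$truth, p("truth.tsv"))
  invisible(out_dir)
}
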