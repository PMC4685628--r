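# Case-control GWAS quality control: sample missingness, heterozygosity
# outliers, duplicate detection by mean IBS, genotype-PCA ancestry
# outliers, then variant missingness, MAF and Hardy-Weinberg filters
# computed on the surviving samples.

#' QC thresholds
#'
#' Defaults follow common array-GWAS practice: samples with >7% missing
#' genotypes or heterozygosity beyond 2 SD of the cohort mean are dropped,
#' near-duplicates (mean IBS >= 0.95) lose their later-indexed member,
#' and samples beyond 6 SD on any of the top 10 genotype PCs are treated
#' as divergent ancestry. Variants are then filtered at >5% missingness,
#' MAF < 1%, and Hardy-Weinberg exact p < 1e-5 in controls.
#'
#' @param sample_missing_max max per-sample missing fraction (strictly
#'   greater is removed).
#' @param het_sd_mult heterozygosity outlier width in SD units; `Inf`
#'   disables the filter.
#' @param dup_ibs_min mean-IBS similarity at or above which a pair is a
#'   duplicate.
#' @param pca_sd_mult,pca_components PCA outlier rule: |score| >
#'   `pca_sd_mult` * SD on any of the top `pca_components` components.
#' @param variant_missing_max max per-variant missing fraction.
#' @param maf_min minimum minor-allele frequency (strictly smaller is
#'   removed).
#' @param hwe_p_min minimum Hardy-Weinberg exact p in controls.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(sample_missing_max = 0.07, het_sd_mult = 2.0,
                          dup_ibs_min = 0.95, pca_sd_mult = 6.0,
                          pca_components = 10L,
                          variant_missing_max = 0.05, maf_min = 0.01,
                          hwe_p_min = 1e-5) {
  stopifnot(sample_missing_max >= 0, sample_missing_max <= 1,
            het_sd_mult >= 0, dup_ibs_min >= 0, dup_ibs_min <= 1,
            pca_sd_mult > 0, pca_components >= 1L,
            variant_missing_max >= 0, variant_missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(sample_missing_max = sample_missing_max,
                 het_sd_mult = het_sd_mult, dup_ibs_min = dup_ibs_min,
                 pca_sd_mult = pca_sd_mult,
                 pca_components = as.integer(pca_components),
                 variant_missing_max = variant_missing_max,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Per-sample missingness and heterozygosity
#'
#' @param ds a [genotype_dataset()].
#' @return data.frame with `id`, `missing_rate` (missing calls / variants)
#'   and `het_rate` (heterozygous calls / non-missing calls; `NaN` for an
#'   all-missing sample, which the missingness filter removes anyway).
#' @export
sample_stats <- function(ds) {
  g <- ds$genotypes
  if (ncol(g) == 0L) stop("dataset has no variants")
  n_miss <- rowSums(is.na(g))
  n_obs <- ncol(g) - n_miss
  data.frame(id = ds$samples$id,
             missing_rate = n_miss / ncol(g),
             het_rate = rowSums(g == 1L, na.rm = TRUE) / n_obs,
             stringsAsFactors = FALSE)
}

#' Per-variant missingness, MAF and Hardy-Weinberg p in controls
#'
#' MAF is folded (`min(f, 1-f)` of the coded-allele frequency) so it is a
#' true minor-allele frequency even after sample subsetting. The HWE exact
#' test uses genotype counts among controls only, the convention that
#' keeps disease-associated departures in cases from being mistaken for
#' genotyping error.
#'
#' @param ds a [genotype_dataset()].
#' @return data.frame with `id`, `missing_rate`, `maf`, `hwe_p_controls`.
#' @export
variant_stats <- function(ds) {
  g <- ds$genotypes
  n <- nrow(g)
  if (n == 0L) stop("dataset has no samples")
  miss <- colSums(is.na(g)) / n
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  ctrl <- g[ds$samples$status == "control", , drop = FALSE]
  nAA <- colSums(ctrl == 0L, na.rm = TRUE)
  nAa <- colSums(ctrl == 1L, na.rm = TRUE)
  naa <- colSums(ctrl == 2L, na.rm = TRUE)
  hwe <- vapply(seq_len(ncol(g)),
                function(j) hwe_exact_test(nAA[j], nAa[j], naa[j]),
                0)
  data.frame(id = ds$variants$id, missing_rate = miss, maf = maf,
             hwe_p_controls = hwe, stringsAsFactors = FALSE)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions for a biallelic
#' genotype table: conditioning on the observed allele counts, the
#' probability of every heterozygote count with the right parity is
#' accumulated, and the p-value is the total probability of tables no more
#' probable than the observed one (no mid-p). Probabilities are computed
#' by the standard two-sided recurrence from the modal heterozygote count,
#' which is numerically stable for large samples.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return p-value in `(0, 1]`. An empty table returns 1 by convention.
#' @examples
#' hwe_exact_test(50, 0, 0)   # monomorphic: 1
#' hwe_exact_test(20, 10, 20) # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0,
            n_AA == round(n_AA), n_Aa == round(n_Aa), n_aa == round(n_aa))
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) return(1)
  rare <- 2L * min(n_AA, n_aa) + n_Aa     # minor allele count
  if (rare == 0L) return(1)
  # modal heterozygote count with matching parity
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  h_max <- if (rare %% 2L == 0L) min(rare, 2L * n - rare) else
    min(rare, 2L * n - rare)
  probs <- numeric(rare + 1L)             # index h+1, only parity slots used
  probs[mid + 1L] <- 1
  # downward recurrence: p(h-2) = p(h) * h(h-1) / (4 (homr+1)(homc+1))
  h <- mid
  while (h >= 2L) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    probs[h - 1L] <- probs[h + 1L] * h * (h - 1) /
      (4 * (homr + 1) * (homc + 1))
    h <- h - 2L
  }
  # upward recurrence: p(h+2) = p(h) * 4 homr homc / ((h+2)(h+1))
  h <- mid
  while (h + 2L <= h_max) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    if (homr <= 0 || homc <= 0) break
    probs[h + 3L] <- probs[h + 1L] * 4 * homr * homc / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[n_Aa + 1L]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(1, p)
}

#' Detect duplicate (or near-duplicate) samples by mean IBS
#'
#' Pairwise similarity is the mean, over co-observed variants, of
#' `(2 - |g_i - g_j|) / 2` (1 for identical genotypes, 0 for opposite
#' homozygotes). Pairs at or above the threshold are duplicates and the
#' later-indexed member is marked for removal. Pairs with no co-observed
#' variant have undefined similarity and are reported separately.
#'
#' @param ds a [genotype_dataset()] with at least two samples.
#' @param dup_ibs_min similarity threshold (default 0.95).
#' @return list with `duplicates` (data.frame `id1`, `id2`, `ibs`,
#'   `remove` = `id2`), and `undefined` (data.frame of incomparable
#'   pairs).
#' @export
detect_duplicates <- function(ds, dup_ibs_min = 0.95) {
  g <- ds$genotypes
  n <- nrow(g)
  if (n < 2L) stop("need at least two samples")
  A <- list(`0` = (!is.na(g)) & g == 0L,
            `1` = (!is.na(g)) & g == 1L,
            `2` = (!is.na(g)) & g == 2L)
  A <- lapply(A, function(x) {x[is.na(x)] <- FALSE; x * 1})
  O <- (!is.na(g)) * 1
  n_co <- O %*% t(O)
  d_sum <- A[["0"]] %*% t(A[["1"]]) + A[["1"]] %*% t(A[["0"]]) +
    A[["1"]] %*% t(A[["2"]]) + A[["2"]] %*% t(A[["1"]]) +
    2 * (A[["0"]] %*% t(A[["2"]]) + A[["2"]] %*% t(A[["0"]]))
  sim <- 1 - d_sum / (2 * n_co)           # NaN where n_co == 0
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  s <- sim[ut]
  ids <- ds$samples$id
  undef <- is.nan(s)
  dup <- !undef & s >= dup_ibs_min
  list(duplicates = data.frame(id1 = ids[ut[dup, 1L]],
                               id2 = ids[ut[dup, 2L]],
                               ibs = s[dup],
                               remove = ids[ut[dup, 2L]],
                               stringsAsFactors = FALSE),
       undefined = data.frame(id1 = ids[ut[undef, 1L]],
                              id2 = ids[ut[undef, 2L]],
                              stringsAsFactors = FALSE))
}

#' Genotype principal components and ancestry outliers
#'
#' Columns are centred by twice the allele frequency and scaled by the
#' binomial SD `sqrt(2 f (1-f))`; missing entries become 0 (the mean)
#' after centring. Monomorphic variants carry no information, and rare
#' variants (MAF below `maf_min`) would dominate single components after
#' the 1/sqrt(f) scaling and flag their few carriers rather than
#' ancestry, so both are excluded (with a warning) — ancestry PCA is
#' conventionally run on common SNPs. A sample is an outlier when any of
#' its top-k scores exceeds `sd_mult` standard deviations of that
#' component's scores.
#'
#' @param ds a [genotype_dataset()].
#' @param k number of components (capped at `min(n, m) - 1`).
#' @param sd_mult outlier width in SD units (default 6).
#' @param maf_min minimum folded MAF for a variant to enter the PCA
#'   (default 0.01).
#' @return list with `scores` (n x k matrix), `sdev`, and `outlier`
#'   (logical per sample).
#' @export
genotype_pca <- function(ds, k = 10L, sd_mult = 6.0, maf_min = 0.01) {
  g <- ds$genotypes
  f <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(f) & pmin(f, 1 - f) >= maf_min
  if (any(!poly))
    warning(sum(!poly), " monomorphic/rare variants excluded from PCA")
  if (sum(poly) < 2L || nrow(g) < 3L)
    return(list(scores = matrix(0, nrow(g), 0L), sdev = numeric(0),
                outlier = rep(FALSE, nrow(g))))
  x <- g[, poly, drop = FALSE]
  f <- f[poly]
  x <- sweep(x, 2L, 2 * f)
  x <- sweep(x, 2L, sqrt(2 * f * (1 - f)), "/")
  x[is.na(x)] <- 0
  k <- min(as.integer(k), nrow(x) - 1L, ncol(x) - 1L)
  sv <- svd(x, nu = k, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  sds <- apply(scores, 2L, sd)
  out <- rep(FALSE, nrow(x))
  for (j in seq_len(k))
    if (sds[j] > 0) out <- out | abs(scores[, j]) > sd_mult * sds[j]
  list(scores = scores, sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1L)),
       outlier = out)
}

#' Apply the full QC cascade
#'
#' Filter order is fixed: (1) sample missingness, (2) heterozygosity
#' outliers with mean/SD computed on the samples surviving step 1,
#' (3) duplicate pairs (later member removed), (4) PCA ancestry outliers;
#' then, on the surviving samples, (5) variant missingness, (6) MAF and
#' (7) Hardy-Weinberg in controls. Samples-before-variants is deliberate:
#' variant statistics must describe the final sample set. Every removal
#' carries exactly one reason code — the first rule in this order that
#' fired.
#'
#' @param ds a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `dataset` (filtered) and `report` (class
#'   `qc_report`): per-sample and per-variant stat tables with `removed`
#'   and `reason` columns, plus before/after counts.
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  th <- thresholds
  ss <- sample_stats(ds)
  ss$removed <- FALSE
  ss$reason <- NA_character_

  mark <- function(ss, ids, reason) {
    new <- ss$id %in% ids & !ss$removed
    ss$removed[new] <- TRUE
    ss$reason[new] <- reason
    ss
  }
  keep_ds <- function(ds, ss, step) {
    kept <- ss$id[!ss$removed]
    if (length(kept) == 0L) stop("no samples remain after ", step, " filter")
    subset_dataset(ds, samples = kept)
  }

  # (1) sample missingness
  ss <- mark(ss, ss$id[ss$missing_rate > th$sample_missing_max],
             "sample_missing")
  cur <- keep_ds(ds, ss, "sample-missingness")

  # (2) heterozygosity outliers, mean/SD on post-step-1 samples
  if (is.finite(th$het_sd_mult)) {
    het <- ss$het_rate[!ss$removed]
    mu <- mean(het, na.rm = TRUE)
    sdv <- sd(het, na.rm = TRUE)
    if (!is.na(sdv) && sdv > 0) {
      bad <- !ss$removed & !is.nan(ss$het_rate) &
        abs(ss$het_rate - mu) > th$het_sd_mult * sdv
      ss <- mark(ss, ss$id[bad], "het_outlier")
      cur <- keep_ds(ds, ss, "heterozygosity")
    }
  }

  # (3) duplicates
  if (nrow(cur$genotypes) >= 2L) {
    dup <- detect_duplicates(cur, th$dup_ibs_min)
    if (nrow(dup$duplicates))
      ss <- mark(ss, unique(dup$duplicates$remove), "duplicate")
    cur <- keep_ds(ds, ss, "duplicate")
  }

  # (4) PCA ancestry outliers
  pca <- suppressWarnings(
    genotype_pca(cur, k = th$pca_components, sd_mult = th$pca_sd_mult))
  if (any(pca$outlier)) {
    ss <- mark(ss, cur$samples$id[pca$outlier], "pca_outlier")
    cur <- keep_ds(ds, ss, "PCA-outlier")
  }

  # (5)-(7) variant filters on the surviving samples
  vs <- variant_stats(cur)
  vs$removed <- FALSE
  vs$reason <- NA_character_
  bad <- vs$missing_rate > th$variant_missing_max
  vs$removed[bad] <- TRUE
  vs$reason[bad] <- "variant_missing"
  bad <- !vs$removed & vs$maf < th$maf_min
  vs$removed[bad] <- TRUE
  vs$reason[bad] <- "low_maf"
  bad <- !vs$removed & vs$hwe_p_controls < th$hwe_p_min
  vs$removed[bad] <- TRUE
  vs$reason[bad] <- "hwe_fail"
  if (all(vs$removed)) stop("no variants remain after variant filters")
  out <- subset_dataset(cur, variants = vs$id[!vs$removed])

  report <- structure(list(
    samples = ss, variants = vs, thresholds = th,
    counts = list(samples_in = nrow(ds$genotypes),
                  samples_out = nrow(out$genotypes),
                  variants_in = ncol(ds$genotypes),
                  variants_out = ncol(out$genotypes))),
    class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cn <- x$counts
  cat(sprintf("QC: %d of %d samples and %d of %d SNPs remained\n",
              cn$samples_out, cn$samples_in, cn$variants_out,
              cn$variants_in))
  if (any(x$samples$removed)) {
    cat("sample removals:\n")
    print(table(x$samples$reason[x$samples$removed]))
  }
  if (any(x$variants$removed)) {
    cat("variant removals:\n")
    print(table(x$variants$reason[x$variants$removed]))
  }
  invisible(x)
}

#' Write a QC report as two TSVs plus a summary line
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param prefix path prefix; writes `<prefix>.qc_samples.tsv`,
#'   `<prefix>.qc_variants.tsv` and `<prefix>.qc_summary.txt`.
#' @export
write_qc_report <- function(report, prefix) {
  data.table::fwrite(report$samples, paste0(prefix, ".qc_samples.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(report$variants, paste0(prefix, ".qc_variants.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  cn <- report$counts
  writeLines(sprintf(
    "After quality control, %d samples and %d SNPs remained (from %d and %d).",
    cn$samples_out, cn$variants_out, cn$samples_in, cn$variants_in),
    paste0(prefix, ".qc_summary.txt"))
  invisible(prefix)
}
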