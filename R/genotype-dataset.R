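#' Construct a genotype dataset
#'
#' The canonical in-memory container for a case-control genotype study: an
#' integer matrix of minor-allele dosages (samples in rows, variants in
#' columns, codes 0/1/2 with `NA` for missing) together with variant and
#' sample metadata tables.
#'
#' Genotype codes count copies of the *minor* allele (`allele_b` in the
#' variant table), so the minor-allele frequency of a variant is
#' `mean(code)/2` over non-missing entries and odds ratios keep a stable
#' orientation across variants.
#'
#' @param genotypes integer matrix, samples x variants, values in
#'   `c(0L, 1L, 2L, NA)`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `allele_a` (major), `allele_b` (minor) and optionally `gene`
#'   (`NA` where unannotated).
#' @param samples data.frame with columns `id`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `age` (years, `NA` allowed)
#'   and `status` (`"case"` or `"control"`).
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `variants`, `samples`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' ds <- genotype_dataset(
#'   g,
#'   variants = data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
#'                         allele_a = "A", allele_b = "G"),
#'   samples  = data.frame(id = c("s1", "s2"), sex = "unknown", age = NA_real_,
#'                         status = c("case", "control")))
#' dim(ds$genotypes)
#' @export
genotype_dataset <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(variants$gene)) variants$gene <- NA_character_
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(genotypes) <- list(samples$id, variants$id)
  ds <- structure(list(genotypes = genotypes, variants = variants,
                       samples = samples),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset's invariants
#'
#' Checks matrix/metadata dimension agreement, the 0/1/2/NA code alphabet,
#' uniqueness of sample and variant ids, positive positions and distinct
#' alleles. Called by every constructor and reader; exported so user code
#' can re-assert after manual surgery.
#'
#' @param ds a `genotype_dataset`.
#' @return `ds`, invisibly. Errors describe the first violated invariant.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  if (nrow(g) != nrow(ds$samples))
    stop("genotype rows (", nrow(g), ") != samples (", nrow(ds$samples), ")")
  if (ncol(g) != nrow(ds$variants))
    stop("genotype cols (", ncol(g), ") != variants (", nrow(ds$variants), ")")
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad)) stop("genotype codes outside {0,1,2,NA}")
  if (anyDuplicated(ds$samples$id)) stop("duplicate sample ids")
  if (anyDuplicated(ds$variants$id)) stop("duplicate variant ids")
  if (nrow(ds$variants) > 0L) {
    if (any(!is.na(ds$variants$pos) & ds$variants$pos < 1))
      stop("variant positions must be >= 1")
    same <- ds$variants$allele_a == ds$variants$allele_b
    if (any(same, na.rm = TRUE))
      stop("allele_a == allele_b for variant ",
           ds$variants$id[which(same)[1L]])
  }
  st <- ds$samples$status
  if (nrow(ds$samples) > 0L && !all(st %in% c("case", "control")))
    stop("sample status must be 'case' or 'control'")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_case <- sum(x$samples$status == "case")
  cat(sprintf(
    "genotype_dataset: %d samples (%d cases / %d controls) x %d variants\n",
    nrow(x$genotypes), n_case, nrow(x$genotypes) - n_case, ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%; gene-annotated variants: %d\n",
              100 * miss, sum(!is.na(x$variants$gene))))
  invisible(x)
}

#' Subset a dataset by sample and/or variant selection
#'
#' @param ds a `genotype_dataset`.
#' @param samples,variants logical, integer or character (id) index into
#'   the respective axis; `NULL` keeps everything.
#' @return the subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, ds$samples$id, "sample")
  vi <- resolve_index(variants, ds$variants$id, "variant")
  genotype_dataset(ds$genotypes[si, vi, drop = FALSE],
                   ds$variants[vi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ", what, " id: ", idx[which(is.na(pos))[1L]])
    return(pos)
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  idx
}

#' Per-variant minor-allele frequency
#'
#' MAF computed as `mean(code)/2` over non-missing genotypes. Because codes
#' count minor-allele copies as oriented on the full pre-QC dataset, values
#' can exceed 0.5 after subsetting samples.
#'
#' @param ds a `genotype_dataset`.
#' @return named numeric vector, `NaN` for all-missing variants.
#' @export
variant_maf <- function(ds) {
  colMeans(ds$genotypes, na.rm = TRUE) / 2
}

#' Swap the allele orientation of selected variants
#'
#' Recodes `g -> 2 - g` (missing stays missing) and swaps
#' `allele_a`/`allele_b`. Used when re-orienting codes to the minor allele.
#'
#' @param ds a `genotype_dataset`.
#' @param variants index of variants to flip (default: all).
#' @return the recoded `genotype_dataset`.
#' @export
swap_alleles <- function(ds, variants = NULL) {
  vi <- resolve_index(variants, ds$variants$id, "variant")
  g <- ds$genotypes
  g[, vi] <- 2L - g[, vi]
  v <- ds$variants
  tmp <- v$allele_a[vi]
  v$allele_a[vi] <- v$allele_b[vi]
  v$allele_b[vi] <- tmp
  genotype_dataset(g, v, ds$samples)
}

# status as 0/1 integer (1 = case)
status01 <- function(ds) as.integer(ds$samples$status == "case")
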