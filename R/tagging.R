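# Tag-SNP reduction: pick a minimal-ish set of variants such that every
# other variant is in strong LD (r-squared above a threshold, within a
# genomic window) with some chosen tag. Greedy most-coverage-first set
# cover, the pairwise-tagging strategy of the classic Tagger approach.

#' Composite LD r-squared between two genotype vectors
#'
#' Squared Pearson correlation of 0/1/2 dosage codes over co-observed
#' samples (composite LD; no haplotype phasing needed). Undefined — and
#' returned as `NA` — when fewer than two samples are co-observed or
#' either variant is monomorphic among them; tagging treats `NA` as 0.
#'
#' @param g1,g2 equal-length integer vectors with codes 0/1/2/`NA`.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Greedy tag-SNP selection
#'
#' Per chromosome, variant `i` covers variant `j` when their positions are
#' within `window_bp` and their dosage r-squared is at least
#' `r2_threshold` (every variant covers itself). Tags are chosen greedily:
#' repeatedly take the variant covering the most still-uncovered variants,
#' breaking ties by smaller position then id, until everything is covered.
#' Variants without a position are their own tags (with a warning).
#'
#' @param ds a [genotype_dataset()].
#' @param r2_threshold minimum r-squared for a tag to represent a variant
#'   (default 0.8).
#' @param window_bp maximum base-pair distance between a variant and its
#'   tag (default 250000).
#' @return a `tag_set`: list with `tags` (character ids), `map`
#'   (data.frame `variant_id`, `tag_id`, `r2`; tags map to themselves with
#'   r2 1), `r2_threshold`, `window_bp`.
#' @export
greedy_tag_selection <- function(ds, r2_threshold = 0.8,
                                 window_bp = 250000) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_bp >= 0)
  v <- ds$variants
  g <- ds$genotypes
  map <- data.frame(variant_id = character(0), tag_id = character(0),
                    r2 = numeric(0), stringsAsFactors = FALSE)
  unplaced <- is.na(v$pos) | is.na(v$chrom)
  if (any(unplaced)) {
    warning(sum(unplaced), " variants without position are their own tags")
    map <- rbind(map, data.frame(variant_id = v$id[unplaced],
                                 tag_id = v$id[unplaced], r2 = 1,
                                 stringsAsFactors = FALSE))
  }
  for (chr in unique(v$chrom[!unplaced])) {
    sel <- which(!unplaced & v$chrom == chr)
    sel <- sel[order(v$pos[sel], v$id[sel])]
    m <- length(sel)
    gm <- g[, sel, drop = FALSE]
    pos <- v$pos[sel]
    ids <- v$id[sel]
    r2 <- suppressWarnings(cor(gm, use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 1
    inwin <- abs(outer(pos, pos, "-")) <= window_bp
    covers <- r2 >= r2_threshold & inwin
    diag(covers) <- TRUE
    uncovered <- rep(TRUE, m)
    while (any(uncovered)) {
      # candidate tags are the still-uncovered variants; each covers itself
      gain <- colSums(covers[uncovered, , drop = FALSE])
      gain[!uncovered] <- -1L
      best <- which(gain == max(gain))
      best <- best[order(pos[best], ids[best])][1L]
      newly <- which(covers[, best] & uncovered)
      map <- rbind(map, data.frame(variant_id = ids[newly],
                                   tag_id = ids[best],
                                   r2 = r2[newly, best],
                                   stringsAsFactors = FALSE))
      uncovered[newly] <- FALSE
    }
  }
  map <- map[match(v$id, map$variant_id), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(tags = sort(unique(map$tag_id)), map = map,
                 r2_threshold = r2_threshold, window_bp = window_bp),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d tags covering %d variants (r2 >= %g, window %g bp)\n",
              length(x$tags), nrow(x$map), x$r2_threshold, x$window_bp))
  invisible(x)
}

#' Write a tag map as TSV (`variant_id`, `tag_id`, `r2`)
#'
#' @param tags a `tag_set` from [greedy_tag_selection()].
#' @param path output file.
#' @export
write_tag_set <- function(tags, path) {
  data.table::fwrite(tags$map, path, sep = "\t", quote = FALSE)
  invisible(path)
}
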