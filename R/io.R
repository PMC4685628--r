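#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the classic PLINK text pair: `.map` rows give variant id, chrom
#' and 1-based position; `.ped` rows are `FID IID PAT MAT SEX PHENO`
#' followed by two allele columns per variant (`0 0` = missing). Genotypes
#' are recoded to minor-allele dosages: per variant the minor allele is the
#' less frequent one in this file (ties broken so that the major
#' `allele_a` is the lexicographically smaller allele), and each sample's
#' code counts its copies of the minor allele.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return a [genotype_dataset()]. Sample sex/status come from the `.ped`
#'   columns (SEX 1=male, 2=female, else unknown; PHENO 1=control,
#'   2=case); age is `NA` (PLINK text carries none — see
#'   [read_sample_table()]).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  if (any(lengths(map_tok) < 4L))
    stop("malformed .map line ", which(lengths(map_tok) < 4L)[1L])
  variants <- data.frame(
    id = vapply(map_tok, `[[`, "", 2L),
    chrom = vapply(map_tok, `[[`, "", 1L),
    pos = as.integer(vapply(map_tok, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * m
  if (any(lengths(ped_tok) != want))
    stop("ragged .ped line ", which(lengths(ped_tok) != want)[1L],
         ": expected ", want, " fields")
  n <- length(ped_tok)
  ped <- matrix(unlist(ped_tok), nrow = n, byrow = TRUE)

  sex_code <- ped[, 5L]
  pheno <- ped[, 6L]
  samples <- data.frame(
    id = ped[, 2L],
    sex = c("1" = "male", "2" = "female")[sex_code],
    age = NA_real_,
    status = c("1" = "control", "2" = "case")[pheno],
    stringsAsFactors = FALSE)
  samples$sex[is.na(samples$sex)] <- "unknown"
  if (anyNA(samples$status))
    stop(".ped PHENO must be 1 (control) or 2 (case); sample ",
         samples$id[which(is.na(samples$status))[1L]])

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- x1 != "0" & x2 != "0"
    al <- sort(unique(c(x1[obs], x2[obs])))
    if (length(al) > 2L)
      stop("non-biallelic site ", variants$id[j], ": alleles ",
           paste(al, collapse = "/"))
    if (length(al) == 0L) al <- c("A", "N")  # all-missing column
    if (length(al) == 1L)
      al <- c(al, setdiff(c("N", "A", "C", "G", "T"), al)[1L])
    cnt1 <- sum(x1[obs] == al[1L]) + sum(x2[obs] == al[1L])
    cnt2 <- sum(x1[obs] == al[2L]) + sum(x2[obs] == al[2L])
    # minor = less frequent; tie -> major (allele_a) is the smaller string,
    # and al is sorted, so the tie case is already in place
    if (cnt2 > cnt1) al <- al[c(2L, 1L)]
    allele_a[j] <- al[1L]; allele_b[j] <- al[2L]
    g[obs, j] <- (x1[obs] == al[2L]) + (x2[obs] == al[2L])
  }
  variants$allele_a <- allele_a
  variants$allele_b <- allele_b
  genotype_dataset(g, variants, samples)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]: dosage 0 becomes `allele_a allele_a`,
#' 1 `allele_a allele_b`, 2 `allele_b allele_b`, missing `0 0`.
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(ds, prefix) {
  v <- ds$variants
  map <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  lines <- character(n)
  sex_code <- c(male = "1", female = "2", unknown = "0")[ds$samples$sex]
  pheno <- c(control = "1", case = "2")[ds$samples$status]
  for (i in seq_len(n)) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, v$allele_b, v$allele_a))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, v$allele_b, v$allele_a))
    lines[i] <- paste(ds$samples$id[i], ds$samples$id[i], "0", "0",
                      sex_code[i], pheno[i],
                      paste(rbind(x1, x2), collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write / read a TSV dosage matrix
#'
#' Plain samples-by-variants table of 0/1/2 codes with missing written as
#' `NA`; first column `sample_id`, remaining columns named by variant id.
#' The round trip is lossless on codes and ids; variant metadata beyond
#' the id is not carried by this format (see [write_dataset()]).
#'
#' @param ds a [genotype_dataset()].
#' @param path file path.
#' @return `read_tsv_matrix` returns a [genotype_dataset()] with
#'   placeholder alleles (`A`/`B`), unknown positions and all samples
#'   marked `control` unless a sample table is attached afterwards.
#' @export
write_tsv_matrix <- function(ds, path) {
  dt <- data.table::data.table(sample_id = ds$samples$id)
  gm <- ds$genotypes
  for (j in seq_len(ncol(gm))) dt[[ds$variants$id[j]]] <- gm[, j]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1L))
  ids <- dt[[1L]]
  g <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(g) && length(g))
    stop("non-integer genotype cells (only 0/1/2/NA allowed)")
  if (length(g) && any(g[!is.na(g)] != as.integer(g[!is.na(g)])))
    stop("non-integer genotype cells (only 0/1/2/NA allowed)")
  vids <- colnames(dt)[-1L]
  storage.mode(g) <- "integer"
  genotype_dataset(
    g,
    data.frame(id = vids, chrom = rep(NA_character_, length(vids)),
               pos = rep(NA_integer_, length(vids)),
               allele_a = rep("A", length(vids)),
               allele_b = rep("B", length(vids)), stringsAsFactors = FALSE),
    data.frame(id = ids, sex = rep("unknown", length(ids)),
               age = rep(NA_real_, length(ids)),
               status = rep("control", length(ids)),
               stringsAsFactors = FALSE))
}

#' Write / read a sample table
#'
#' TSV with columns `id`, `sex`, `age`, `status` — the covariate sheet
#' accompanying a genotype file.
#'
#' @param samples data.frame in the `genotype_dataset` sample layout (or a
#'   whole dataset, whose `$samples` is used).
#' @param path file path.
#' @export
write_sample_table <- function(samples, path) {
  if (inherits(samples, "genotype_dataset")) samples <- samples$samples
  data.table::fwrite(samples, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  s <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                       colClasses = list(character = "id")))
  need <- c("id", "sex", "age", "status")
  if (!all(need %in% names(s)))
    stop("sample table must have columns ", paste(need, collapse = ", "))
  s
}

#' Write / read a full dataset as a TSV trio
#'
#' Lossless dataset persistence: `<prefix>.geno.tsv` (dosage matrix),
#' `<prefix>.variants.tsv`, `<prefix>.samples.tsv`.
#'
#' @param ds a [genotype_dataset()].
#' @param prefix path prefix.
#' @export
write_dataset <- function(ds, prefix) {
  write_tsv_matrix(ds, paste0(prefix, ".geno.tsv"))
  data.table::fwrite(ds$variants, paste0(prefix, ".variants.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  write_sample_table(ds$samples, paste0(prefix, ".samples.tsv"))
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  ds <- read_tsv_matrix(paste0(prefix, ".geno.tsv"))
  v <- as.data.frame(data.table::fread(
    paste0(prefix, ".variants.tsv"), sep = "\t", na.strings = "NA",
    colClasses = list(character = c("id", "chrom", "allele_a", "allele_b"))))
  s <- read_sample_table(paste0(prefix, ".samples.tsv"))
  stopifnot(identical(v$id, ds$variants$id), identical(s$id, ds$samples$id))
  genotype_dataset(ds$genotypes, v, s)
}

#' Read a SNP-to-gene annotation (TSV or BED)
#'
#' Two accepted layouts: a two-column TSV `snp_id<TAB>gene`, or a BED file
#' `chrom start end gene` with 0-based half-open intervals. The format is
#' detected from the first data row (numeric columns 2-3 with >= 4 columns
#' means BED).
#'
#' @param path annotation file.
#' @return an object of class `gene_annotation`: a list with `kind`
#'   (`"tsv"` or `"bed"`) and `table`.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  if (length(tok) == 0L)
    return(structure(list(kind = "tsv",
                          table = data.frame(snp_id = character(),
                                             gene = character())),
                     class = "gene_annotation"))
  first <- tok[[1L]]
  is_bed <- length(first) >= 4L &&
    !is.na(suppressWarnings(as.numeric(first[2L]))) &&
    !is.na(suppressWarnings(as.numeric(first[3L])))
  if (is_bed) {
    bad <- which(lengths(tok) < 4L)
    if (length(bad)) stop("malformed BED row at line ", bad[1L])
    tab <- data.frame(
      chrom = vapply(tok, `[[`, "", 1L),
      start = as.numeric(vapply(tok, `[[`, "", 2L)),
      end = as.numeric(vapply(tok, `[[`, "", 3L)),
      gene = vapply(tok, `[[`, "", 4L),
      stringsAsFactors = FALSE)
    if (anyNA(tab$start) || anyNA(tab$end))
      stop("malformed BED row at line ",
           which(is.na(tab$start) | is.na(tab$end))[1L])
    kind <- "bed"
  } else {
    bad <- which(lengths(tok) < 2L)
    if (length(bad)) stop("malformed annotation row at line ", bad[1L])
    tab <- data.frame(snp_id = vapply(tok, `[[`, "", 1L),
                      gene = vapply(tok, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
    kind <- "tsv"
  }
  structure(list(kind = kind, table = tab), class = "gene_annotation")
}

#' Apply a gene annotation to a dataset
#'
#' TSV annotations match by variant id. BED intervals are 0-based
#' half-open, so a variant at 1-based position `p` on the right chromosome
#' is labelled by an interval `[start, end)` iff `start < p <= end`. When
#' several rows match, the first wins.
#'
#' @param ds a [genotype_dataset()].
#' @param ann a `gene_annotation` from [read_gene_annotation()].
#' @return the dataset with `variants$gene` filled in (unmatched variants
#'   keep `NA`).
#' @export
annotate_genes <- function(ds, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  v <- ds$variants
  if (ann$kind == "tsv") {
    hit <- match(v$id, ann$table$snp_id)
    v$gene <- ifelse(is.na(hit), v$gene, ann$table$gene[hit])
  } else {
    for (i in seq_len(nrow(v))) {
      if (is.na(v$pos[i]) || is.na(v$chrom[i])) next
      m <- which(ann$table$chrom == v$chrom[i] &
                   ann$table$start < v$pos[i] &
                   v$pos[i] <= ann$table$end)
      if (length(m)) v$gene[i] <- ann$table$gene[m[1L]]
    }
  }
  ds$variants <- v
  ds
}
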