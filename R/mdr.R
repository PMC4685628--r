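# Exhaustive pairwise multifactor-dimensionality reduction (MDR).
# Each SNP pair defines a 3x3 joint-genotype grid; training cells are
# labelled high- or low-risk by their case:control ratio, turning the pair
# into a one-dimensional classifier whose held-out balanced accuracy,
# averaged over stratified 10-fold cross-validation, is the pair's
# cross-validation value (CVV). Chance performance is 0.5 regardless of
# class imbalance, so pairs with CVV > 0.5 are called significant.

#' MDR scan configuration
#'
#' @param n_folds number of cross-validation folds (default 10).
#' @param ratio_threshold case:control ratio above which a training cell
#'   is high-risk. Default `NULL`: use each training split's own
#'   case:control ratio, the standard choice for unbalanced cohorts.
#' @param empty_cell_policy what a test sample falling in an empty
#'   training cell (or with a missing genotype) counts as:
#'   `"low_risk"` (predicted control; deterministic and conservative) or
#'   `"unknown_misclassified"`.
#' @param cvv_threshold significance cut on CVV (strict `>`; default 0.5,
#'   chance level for balanced accuracy).
#' @param top_n how many ranked pairs [scan_pairs()] retains
#'   (`NULL` = all).
#' @param seed integer seed for fold assignment.
#' @return an `mdr_config` list.
#' @export
mdr_config <- function(n_folds = 10L, ratio_threshold = NULL,
                       empty_cell_policy = c("low_risk",
                                             "unknown_misclassified"),
                       cvv_threshold = 0.5, top_n = NULL, seed = 1L) {
  empty_cell_policy <- match.arg(empty_cell_policy)
  stopifnot(n_folds >= 2L, cvv_threshold >= 0, cvv_threshold <= 1,
            is.null(ratio_threshold) ||
              (is.numeric(ratio_threshold) && ratio_threshold > 0),
            is.null(top_n) || top_n >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 ratio_threshold = ratio_threshold,
                 empty_cell_policy = empty_cell_policy,
                 cvv_threshold = cvv_threshold,
                 top_n = if (is.null(top_n)) NULL else as.integer(top_n),
                 seed = as.integer(seed)),
            class = "mdr_config")
}

# fold assignment from the live RNG stream; cyclic within each class so
# per-class fold counts differ by at most one, and the control cycle
# starts where the case cycle stopped so folds stay as even as possible
# even when n_folds approaches n (leave-one-out).
.make_folds_stream <- function(status01, n_folds) {
  n <- length(status01)
  if (n_folds > n) stop("more folds than samples")
  folds <- integer(n)
  cases <- which(status01 == 1L)
  ctrls <- which(status01 == 0L)
  cases <- cases[sample.int(length(cases))]
  ctrls <- ctrls[sample.int(length(ctrls))]
  folds[cases] <- ((seq_along(cases) - 1L) %% n_folds) + 1L
  folds[ctrls] <- ((seq_along(ctrls) - 1L + length(cases)) %% n_folds) + 1L
  folds
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `n_folds` folds so that fold sizes
#' within each class differ by at most one, deterministically under
#' `seed`.
#'
#' @param status character (`"case"`/`"control"`) or 0/1 vector.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold labels in `1:n_folds`.
#' @export
make_folds <- function(status, n_folds = 10L, seed = 1L) {
  s01 <- if (is.character(status)) as.integer(status == "case")
  else as.integer(status)
  stopifnot(all(s01 %in% c(0L, 1L)))
  with_seed(seed, .make_folds_stream(s01, as.integer(n_folds)))
}

#' Fit an MDR risk grid on training data
#'
#' Counts cases and controls per joint-genotype cell (samples with a
#' missing genotype at either locus are excluded from counting) and
#' labels each cell `high` when its case:control ratio reaches `T`
#' (a cell with cases but no controls is `high`; a cell with neither is
#' `empty`).
#'
#' @param g1,g2 genotype codes (0/1/2/`NA`) of the two loci.
#' @param status case/control labels (character or 0/1).
#' @param T risk-ratio threshold, e.g. the cohort case:control ratio.
#' @return a `risk_grid`: list with 3x3 `cases`, `controls`, and
#'   `label` (`"high"`/`"low"`/`"empty"`) matrices.
#' @export
fit_risk_grid <- function(g1, g2, status, T) {
  s01 <- if (is.character(status)) as.integer(status == "case")
  else as.integer(status)
  stopifnot(T > 0, length(g1) == length(g2), length(g1) == length(s01))
  .fit_grid(g1, g2, s01, num = T, den = 1)
}

# internal: T expressed as num/den so the default training-ratio threshold
# compares by cross-multiplication, identically to the C++ scan core.
.fit_grid <- function(g1, g2, s01, num, den) {
  ok <- !is.na(g1) & !is.na(g2)
  cases <- matrix(0L, 3L, 3L, dimnames = list(g1 = 0:2, g2 = 0:2))
  controls <- cases
  for (i in which(ok)) {
    r <- g1[i] + 1L; c <- g2[i] + 1L
    if (s01[i] == 1L) cases[r, c] <- cases[r, c] + 1L
    else controls[r, c] <- controls[r, c] + 1L
  }
  label <- matrix("low", 3L, 3L, dimnames = dimnames(cases))
  label[cases == 0L & controls == 0L] <- "empty"
  high <- cases * den >= controls * num & !(cases == 0L & controls == 0L)
  label[high] <- "high"
  structure(list(cases = cases, controls = controls, label = label,
                 T = num / den),
            class = "risk_grid")
}

# classify samples with a fitted grid; returns predicted 0/1
.classify_grid <- function(grid, g1, g2, s01, policy) {
  lab <- ifelse(is.na(g1) | is.na(g2), "empty",
                grid$label[cbind(g1 + 1L, g2 + 1L)])
  pred <- integer(length(g1))
  pred[lab == "high"] <- 1L
  pred[lab == "low"] <- 0L
  und <- lab == "empty"
  pred[und] <- if (policy == "low_risk") 0L else 1L - s01[und]
  pred
}

.balanced_accuracy <- function(pred, s01) {
  n_case <- sum(s01 == 1L); n_ctrl <- sum(s01 == 0L)
  sens <- if (n_case > 0L) sum(pred == 1L & s01 == 1L) / n_case else NA_real_
  spec <- if (n_ctrl > 0L) sum(pred == 0L & s01 == 0L) / n_ctrl else NA_real_
  if (n_case > 0L && n_ctrl > 0L) (sens + spec) / 2
  else if (n_case > 0L) sens
  else spec
}

#' Evaluate one SNP pair by cross-validated MDR
#'
#' For each fold, a risk grid is fitted on the other folds (the
#' high-risk threshold defaulting to that training split's case:control
#' ratio) and the held-out samples are classified high-risk = case,
#' low-risk = control; the CVV is the mean held-out balanced accuracy.
#'
#' @param ds a [genotype_dataset()].
#' @param pair two variant ids or column indices.
#' @param config an [mdr_config()].
#' @return an `mdr_model`: list with `id1`, `id2`, `gene1`, `gene2`,
#'   `folds`, per-fold `grids`, `train_ba`, `test_ba`, `cvv`,
#'   `significant`, plus a `degenerate_folds` flag for folds missing a
#'   class in the held-out set.
#' @export
evaluate_pair <- function(ds, pair, config = mdr_config()) {
  stopifnot(inherits(config, "mdr_config"))
  vi <- resolve_index(pair, ds$variants$id, "variant")
  stopifnot(length(vi) == 2L, vi[1L] != vi[2L])
  s01 <- status01(ds)
  folds <- make_folds(s01, config$n_folds, config$seed)
  g1 <- ds$genotypes[, vi[1L]]
  g2 <- ds$genotypes[, vi[2L]]
  grids <- vector("list", config$n_folds)
  train_ba <- test_ba <- rep(NA_real_, config$n_folds)
  degenerate <- rep(FALSE, config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    te <- !tr
    if (is.null(config$ratio_threshold)) {
      num <- sum(s01[tr] == 1L); den <- sum(s01[tr] == 0L)
    } else {
      num <- config$ratio_threshold; den <- 1
    }
    grid <- .fit_grid(g1[tr], g2[tr], s01[tr], num, den)
    grids[[f]] <- grid
    pr_tr <- .classify_grid(grid, g1[tr], g2[tr], s01[tr],
                            config$empty_cell_policy)
    train_ba[f] <- .balanced_accuracy(pr_tr, s01[tr])
    pr_te <- .classify_grid(grid, g1[te], g2[te], s01[te],
                            config$empty_cell_policy)
    test_ba[f] <- .balanced_accuracy(pr_te, s01[te])
    degenerate[f] <- sum(s01[te] == 1L) == 0L || sum(s01[te] == 0L) == 0L
  }
  ba_ok <- test_ba[!is.na(test_ba)]
  cvv <- sum(ba_ok) / length(ba_ok)
  structure(list(id1 = ds$variants$id[vi[1L]], id2 = ds$variants$id[vi[2L]],
                 gene1 = ds$variants$gene[vi[1L]],
                 gene2 = ds$variants$gene[vi[2L]],
                 folds = folds, grids = grids, train_ba = train_ba,
                 test_ba = test_ba, cvv = cvv,
                 significant = cvv > config$cvv_threshold,
                 degenerate_folds = degenerate, config = config),
            class = "mdr_model")
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("mdr_model %s x %s: CVV %.3f (%ssignificant at > %g)\n",
              x$id1, x$id2, x$cvv, if (x$significant) "" else "not ",
              x$config$cvv_threshold))
  invisible(x)
}

#' Pair universe for an MDR scan
#'
#' All unordered pairs of the selected variants, optionally restricted to
#' tag SNPs and/or gene-mapped SNPs (the default universe of the
#' pipeline; set both to `FALSE`/`NULL` for an all-pairs scan).
#'
#' @param ds a [genotype_dataset()].
#' @param tags a `tag_set` (or character ids) restricting the universe to
#'   tag SNPs; `NULL` = no restriction.
#' @param gene_mapped keep only variants with a gene annotation.
#' @return integer matrix with two columns of variant indices.
#' @export
pair_universe <- function(ds, tags = NULL, gene_mapped = FALSE) {
  keep <- rep(TRUE, ncol(ds$genotypes))
  if (!is.null(tags)) {
    tag_ids <- if (inherits(tags, "tag_set")) tags$tags else tags
    keep <- keep & ds$variants$id %in% tag_ids
  }
  if (gene_mapped) keep <- keep & !is.na(ds$variants$gene)
  idx <- which(keep)
  if (length(idx) < 2L) stop("empty pair universe")
  pairs <- t(utils::combn(idx, 2L))
  storage.mode(pairs) <- "integer"
  pairs
}

#' Exhaustive MDR scan over a pair universe
#'
#' Evaluates every pair (the compute core is compiled; see
#' [evaluate_pair()] for the per-pair definition) and ranks by CVV
#' descending, ties broken lexicographically by ids. The scan is a pure
#' map: results are identical for any `workers` value.
#'
#' @param ds a [genotype_dataset()].
#' @param pairs 2-column matrix of variant indices (or ids), e.g. from
#'   [pair_universe()]; `NULL` scans all pairs of variants in `ds`.
#' @param config an [mdr_config()].
#' @param workers number of parallel workers (forked; >1 needs a unix
#'   platform, otherwise falls back to serial).
#' @return data.frame ranked by CVV: `id1`, `id2`, `gene1`, `gene2`,
#'   `cvv`, `significant`, truncated to `config$top_n` when set.
#' @export
scan_pairs <- function(ds, pairs = NULL, config = mdr_config(),
                       workers = 1L) {
  stopifnot(inherits(config, "mdr_config"))
  if (is.null(pairs)) pairs <- pair_universe(ds)
  if (is.character(pairs)) pairs <- matrix(
    match(pairs, ds$variants$id), ncol = 2L)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  stopifnot(ncol(pairs) == 2L, nrow(pairs) >= 1L,
            all(pairs >= 1L), all(pairs <= ncol(ds$genotypes)))
  s01 <- status01(ds)
  folds <- make_folds(s01, config$n_folds, config$seed)
  cvv <- .scan_cvv(ds$genotypes, s01, folds, pairs, config, workers)
  out <- data.frame(
    id1 = ds$variants$id[pairs[, 1L]], id2 = ds$variants$id[pairs[, 2L]],
    gene1 = ds$variants$gene[pairs[, 1L]],
    gene2 = ds$variants$gene[pairs[, 2L]],
    cvv = cvv, stringsAsFactors = FALSE)
  out$significant <- out$cvv > config$cvv_threshold
  out <- out[order(-out$cvv, out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(config$top_n)) out <- utils::head(out, config$top_n)
  out
}

# shared C++ dispatch; chunks the pair list across workers (pure map)
.scan_cvv <- function(G, s01, folds, pairs, config, workers = 1L) {
  use_ratio <- is.null(config$ratio_threshold)
  thr <- if (use_ratio) 0 else config$ratio_threshold
  policy <- if (config$empty_cell_policy == "low_risk") 0L else 1L
  run <- function(px) cpp_scan_cvv(G, s01, folds, config$n_folds,
                                   px - 1L, use_ratio, thr, policy)
  workers <- as.integer(workers)
  if (workers <= 1L || .Platform$OS.type != "unix" || nrow(pairs) < 2L)
    return(run(pairs))
  chunks <- split(seq_len(nrow(pairs)),
                  cut(seq_len(nrow(pairs)), min(workers, nrow(pairs)),
                      labels = FALSE))
  res <- parallel::mclapply(chunks, function(ix)
    run(pairs[ix, , drop = FALSE]), mc.cores = workers)
  unlist(res, use.names = FALSE)
}

#' Filter MDR models by CVV significance
#'
#' Strict inequality: a pair at exactly the threshold is not significant.
#'
#' @param models data.frame from [scan_pairs()].
#' @param cvv_threshold CVV cut (default 0.5).
#' @return the significant subset, order preserved.
#' @export
significance_filter <- function(models, cvv_threshold = 0.5) {
  models[!is.na(models$cvv) & models$cvv > cvv_threshold, , drop = FALSE]
}

#' Per-pair permutation null for the CVV
#'
#' Phenotype labels are permuted across the whole cohort, folds are
#' re-drawn on the permuted labels, and the pair is re-scored;
#' `p = (1 + #\{permuted CVV >= observed\}) / (n_perm + 1)`. This tests a
#' single, pre-specified pair. For pairs selected as the top of a scan
#' this p-value is anti-conservative by construction — use
#' [scan_permutation_null()] there.
#'
#' @param ds a [genotype_dataset()].
#' @param pair two variant ids or indices.
#' @param n_perm number of permutations (>= 100).
#' @param config an [mdr_config()].
#' @param seed integer seed for the permutation stream.
#' @return list with `p`, `observed_cvv`, `perm_cvv`.
#' @export
permutation_null <- function(ds, pair, n_perm = 199L,
                             config = mdr_config(), seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- evaluate_pair(ds, pair, config)$cvv
  vi <- resolve_index(pair, ds$variants$id, "variant")
  pairs <- matrix(as.integer(vi), 1L, 2L)
  s01 <- status01(ds)
  perm_cvv <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sp <- s01[sample.int(length(s01))]
      fb <- .make_folds_stream(sp, config$n_folds)
      .scan_cvv(ds$genotypes, sp, fb, pairs, config)
    }, 0)
  })
  list(p = (1 + sum(perm_cvv >= obs)) / (n_perm + 1),
       observed_cvv = obs, perm_cvv = perm_cvv)
}

#' Scan-level (max-statistic) permutation null
#'
#' Permutes phenotype labels and re-runs the whole pair scan each time,
#' recording the maximum CVV. Comparing an observed pair's CVV against
#' this null distribution of scan maxima gives a familywise-adjusted
#' empirical p-value that remains valid for pairs picked *because* they
#' topped the ranking — the standard way MDR results are permutation
#' tested.
#'
#' @param ds a [genotype_dataset()].
#' @param pairs pair universe matrix (see [scan_pairs()]); `NULL` = all
#'   pairs.
#' @param config an [mdr_config()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `max_cvv` (length `n_perm`) and function
#'   `p_adjusted(cvv)` returning `(1 + #\{max >= cvv\}) / (n_perm + 1)`.
#' @export
scan_permutation_null <- function(ds, pairs = NULL, config = mdr_config(),
                                  n_perm = 99L, seed = 1L) {
  if (is.null(pairs)) pairs <- pair_universe(ds)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  s01 <- status01(ds)
  max_cvv <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sp <- s01[sample.int(length(s01))]
      fb <- .make_folds_stream(sp, config$n_folds)
      max(.scan_cvv(ds$genotypes, sp, fb, pairs, config))
    }, 0)
  })
  list(max_cvv = max_cvv,
       p_adjusted = function(cvv)
         (1 + vapply(cvv, function(x) sum(max_cvv >= x), 0L)) / (n_perm + 1))
}
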