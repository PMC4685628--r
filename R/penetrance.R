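#' Build a two-locus penetrance model
#'
#' A penetrance model is a 3x3 table of disease probabilities
#' `P(case | g1, g2)` indexed by the minor-allele dosages (0/1/2) of two
#' loci. It is the generative truth used by [simulate_cohort()] to plant
#' epistatic signal, and the reference against which detection power is
#' judged.
#'
#' Model kinds:
#' \describe{
#'   \item{`null`}{every cell equals `baseline`; `effect` is ignored.}
#'   \item{`xor`}{checkerboard epistasis: cells where `g1 + g2` is odd get
#'     `baseline + effect`, the rest `baseline`. Marginal effects are weak
#'     unless the MAFs are extreme, making it the canonical hard case for
#'     single-SNP tests.}
#'   \item{`threshold`}{`baseline + effect` wherever both loci carry at
#'     least one minor allele (`g1 >= 1 & g2 >= 1`), a jointly dominant
#'     interaction.}
#'   \item{`multiplicative`}{`effect` acts as a relative risk applied once
#'     per locus carrying a minor allele:
#'     `min(1, baseline * effect^((g1 > 0) + (g2 > 0)))`. Multiplicative on
#'     the risk scale, i.e. no interaction beyond the margins.}
#'   \item{`marginal_additive`}{`min(1, baseline + effect * (g1 + g2) / 4)`,
#'     a purely additive dosage model reaching `baseline + effect` at the
#'     double-homozygote.}
#' }
#'
#' @param kind one of `"null"`, `"xor"`, `"threshold"`, `"multiplicative"`,
#'   `"marginal_additive"`.
#' @param baseline baseline penetrance in `[0, 1]`.
#' @param effect penetrance increment (or relative risk for
#'   `multiplicative`); `baseline + effect` must stay in `[0, 1]` for the
#'   additive kinds.
#' @param maf1,maf2 minor-allele frequencies of the two loci, in
#'   `(0, 0.5]`.
#' @param label free-text tag carried into reports.
#' @return a `penetrance_model`: list with `kind`, `table` (3x3, rows =
#'   `g1`, cols = `g2`, dimnames `"0".."2"`), `maf1`, `maf2`, `label`.
#' @examples
#' make_penetrance_model("xor", baseline = 0.05, effect = 0.45,
#'                       maf1 = 0.3, maf2 = 0.3)$table
#' @export
make_penetrance_model <- function(kind, baseline, effect = 0,
                                  maf1 = 0.3, maf2 = 0.3, label = kind) {
  kinds <- c("null", "xor", "threshold", "multiplicative",
             "marginal_additive")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("invalid penetrance kind; must be one of ",
         paste(kinds, collapse = ", "))
  if (baseline < 0 || baseline > 1) stop("baseline outside [0,1]")
  for (m in c(maf1, maf2))
    if (m <= 0 || m > 0.5) stop("MAF must lie in (0, 0.5]")
  g1 <- matrix(0:2, 3, 3)
  g2 <- t(g1)
  tab <- switch(kind,
    null = matrix(baseline, 3, 3),
    xor = baseline + effect * ((g1 + g2) %% 2L == 1L),
    threshold = baseline + effect * (g1 >= 1L & g2 >= 1L),
    multiplicative = matrix(
      pmin(1, baseline * effect^((g1 > 0L) + (g2 > 0L))), 3, 3),
    marginal_additive = matrix(
      pmin(1, baseline + effect * (g1 + g2) / 4), 3, 3))
  if (any(tab < 0 | tab > 1))
    stop("penetrance out of range: baseline=", baseline,
         " effect=", effect, " gives cells outside [0,1]")
  dimnames(tab) <- list(g1 = 0:2, g2 = 0:2)
  structure(list(kind = kind, table = tab, maf1 = maf1, maf2 = maf2,
                 label = label),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance_model '%s' (%s), MAFs %.3g / %.3g\n",
              x$label, x$kind, x$maf1, x$maf2))
  print(round(x$table, 4))
  invisible(x)
}
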