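# Conventional single-SNP case-control association: allelic counts and
# frequencies, odds ratios with Woolf confidence intervals, 1-df allelic
# chi-square, covariate-adjusted additive logistic regression,
# Benjamini-Hochberg correction and genomic-control diagnostics.

#' Allelic 2x2 table for one variant
#'
#' Minor/major allele counts split by case-control status, counting two
#' alleles per genotyped sample (missing genotypes excluded).
#'
#' @param ds a [genotype_dataset()].
#' @param variant variant id or column index.
#' @return list with `counts` (2x2 matrix, rows minor/major, columns
#'   case/control), `freq_cases`, `freq_controls` (minor-allele
#'   frequencies). Errors if either group has no genotyped sample.
#' @export
allele_table <- function(ds, variant) {
  vi <- resolve_index(variant, ds$variants$id, "variant")
  stopifnot(length(vi) == 1L)
  g <- ds$genotypes[, vi]
  case <- ds$samples$status == "case"
  for (grp in c(TRUE, FALSE)) {
    if (all(is.na(g[case == grp])))
      stop("variant ", ds$variants$id[vi], ": no genotyped ",
           if (grp) "cases" else "controls")
  }
  minor_ca <- sum(g[case], na.rm = TRUE)
  tot_ca <- 2L * sum(!is.na(g[case]))
  minor_co <- sum(g[!case], na.rm = TRUE)
  tot_co <- 2L * sum(!is.na(g[!case]))
  counts <- matrix(c(minor_ca, tot_ca - minor_ca,
                     minor_co, tot_co - minor_co), 2L, 2L,
                   dimnames = list(allele = c("minor", "major"),
                                   status = c("case", "control")))
  list(counts = counts,
       freq_cases = minor_ca / tot_ca,
       freq_controls = minor_co / tot_co)
}

#' Odds ratio from group allele frequencies
#'
#' `OR = [f_ca / (1 - f_ca)] / [f_co / (1 - f_co)]`. This is the form that
#' reproduces published ORs from printed frequency columns.
#'
#' @param freq_cases,freq_controls frequencies strictly inside `(0, 1)`.
#' @return the odds ratio (numeric scalar).
#' @examples
#' odds_ratio(0.03704, 0.02586)  # ~1.449
#' @export
odds_ratio <- function(freq_cases, freq_controls) {
  if (any(c(freq_cases, freq_controls) <= 0) ||
      any(c(freq_cases, freq_controls) >= 1))
    stop("frequencies must lie strictly inside (0, 1)")
  (freq_cases / (1 - freq_cases)) / (freq_controls / (1 - freq_controls))
}

#' Odds ratio with Woolf 95% CI from a 2x2 count table
#'
#' `OR = ad / bc` with the log-scale (Woolf) interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell
#' the interval is undefined unless the Haldane-Anscombe continuity
#' correction (+0.5 to every cell) is enabled.
#'
#' @param a,b minor/major allele counts in cases.
#' @param c,d minor/major allele counts in controls.
#' @param correction add 0.5 to every cell (default `FALSE`).
#' @return list with `or`, `ci_lo`, `ci_hi` (`NA` bounds when a zero cell
#'   is present and `correction = FALSE`).
#' @export
odds_ratio_counts <- function(a, b, c, d, correction = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (any(c(a, b, c, d) == 0))
    return(list(or = if (b > 0 && c > 0) (a * d) / (b * c) else NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_))
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_lo = or * exp(-1.959963984540054 * se),
       ci_hi = or * exp(1.959963984540054 * se))
}

#' Allelic chi-square test on a 2x2 table
#'
#' 1-df Pearson chi-square without continuity correction,
#' `n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. A zero margin yields
#' statistic 0 and p = 1 by convention.
#'
#' @param counts 2x2 numeric matrix (e.g. `allele_table()$counts`).
#' @return list with `statistic` and `p`.
#' @export
allelic_test <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2L), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty table")
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) return(list(statistic = 0, p = 1))
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Covariate-adjusted additive logistic association
#'
#' Per variant, fits `status ~ dosage + sex + age` (or any subset of the
#' two covariates) by iteratively reweighted least squares
#' (`stats::glm`, binomial link, tolerance 1e-8, at most 50 iterations)
#' and reports the Wald test for the dosage term. Variants whose fit does
#' not converge, or that show separation-scale estimates
#' (`|beta| > 10` or `SE > 10`), or that are constant among the usable
#' samples, are flagged and get `NA` p-values.
#'
#' @param ds a [genotype_dataset()].
#' @param covariates character subset of `c("sex", "age")`. Samples with
#'   unknown values for a requested covariate are dropped from every fit.
#' @return data.frame with `id`, `beta`, `se`, `p`, `flag`
#'   (`"ok"`, `"constant"`, `"not_converged"`, `"separation"`).
#' @export
logistic_assoc <- function(ds, covariates = c("sex", "age")) {
  stopifnot(all(covariates %in% c("sex", "age")))
  y <- status01(ds)
  covs <- list()
  if ("sex" %in% covariates) {
    sexn <- ifelse(ds$samples$sex == "unknown", NA_real_,
                   as.numeric(ds$samples$sex == "female"))
    covs$sex <- sexn
  }
  if ("age" %in% covariates) covs$age <- as.numeric(ds$samples$age)
  base_ok <- rep(TRUE, length(y))
  for (cv in covs) base_ok <- base_ok & !is.na(cv)

  fit_one <- function(g) {
    ok <- base_ok & !is.na(g)
    if (sum(ok) < length(covs) + 2L || var(g[ok]) == 0)
      return(c(NA, NA, NA, 1))
    dat <- data.frame(y = y[ok], g = g[ok])
    for (nm in names(covs)) dat[[nm]] <- covs[[nm]][ok]
    fit <- suppressWarnings(stats::glm(
      y ~ ., family = stats::binomial(), data = dat,
      control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
    cf <- summary(fit)$coefficients
    if (!("g" %in% rownames(cf))) return(c(NA, NA, NA, 1))
    beta <- cf["g", 1]; se <- cf["g", 2]; p <- cf["g", 4]
    if (!fit$converged) return(c(beta, se, NA, 2))
    if (abs(beta) > 10 || se > 10) return(c(beta, se, NA, 3))
    c(beta, se, p, 0)
  }
  res <- t(apply(ds$genotypes, 2L, fit_one))
  data.frame(id = ds$variants$id,
             beta = res[, 1], se = res[, 2], p = res[, 3],
             flag = c("ok", "constant", "not_converged",
                      "separation")[res[, 4] + 1L],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), preserving input
#' order. Inputs outside `(0, 1]` are an error; `NA`s pass through.
#'
#' @param p numeric vector of nominal p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic-control lambda and QQ/Manhattan coordinates
#'
#' `lambda_gc` is the median 1-df chi-square quantile of the p-values
#' divided by the null median (0.4549...); values near 1 indicate no
#' inflation. QQ coordinates are expected `-log10((i - 0.5) / m)` versus
#' observed sorted `-log10 p`.
#'
#' @param p at least 10 p-values in `(0, 1]`.
#' @param variants optional data.frame with `chrom` and `pos` aligned to
#'   `p`, enabling Manhattan coordinates (cumulative position across
#'   chromosomes in input order).
#' @return list with `lambda_gc`, `qq` (data.frame `expected`,
#'   `observed`), and `manhattan` (or `NULL`).
#' @export
qq_lambda <- function(p, variants = NULL) {
  p <- p[!is.na(p)]
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  m <- length(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sort(p)))
  man <- NULL
  if (!is.null(variants)) {
    stopifnot(nrow(variants) == m)
    offs <- 0
    cum <- numeric(m)
    for (chr in unique(variants$chrom)) {
      sel <- variants$chrom == chr
      cum[sel] <- offs + variants$pos[sel]
      offs <- max(cum[sel]) + 1
    }
    man <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      cum_pos = cum, neglog10_p = -log10(p))
  }
  list(lambda_gc = lambda, qq = qq, manhattan = man)
}

#' Single-SNP association table for every variant
#'
#' The conventional GWAS stage: per variant, allelic counts and
#' frequencies by status, odds ratio with Woolf 95% CI, allelic
#' chi-square p, and BH-adjusted p across all variants. Optionally also
#' runs the covariate-adjusted logistic model.
#'
#' @param ds a [genotype_dataset()].
#' @param adjusted also fit `logistic_assoc()` and append `beta`/`p_logistic`.
#' @param correction continuity correction for ORs with zero cells.
#' @return data.frame, one row per variant: `id`, `gene`, `freq_cases`,
#'   `freq_controls`, `or`, `ci_lo`, `ci_hi`, `p_nominal`, `p_adjusted`
#'   (+ logistic columns when requested).
#' @export
single_snp_association <- function(ds, adjusted = FALSE,
                                   correction = FALSE) {
  m <- ncol(ds$genotypes)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    at <- allele_table(ds, j)
    cn <- at$counts
    orci <- odds_ratio_counts(cn[1, 1], cn[2, 1], cn[1, 2], cn[2, 2],
                              correction = correction)
    tst <- allelic_test(cn)
    rows[[j]] <- data.frame(
      id = ds$variants$id[j], gene = ds$variants$gene[j],
      freq_cases = at$freq_cases, freq_controls = at$freq_controls,
      or = orci$or, ci_lo = orci$ci_lo, ci_hi = orci$ci_hi,
      p_nominal = tst$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_nominal)
  if (adjusted) {
    la <- logistic_assoc(ds)
    out$beta_logistic <- la$beta
    out$p_logistic <- la$p
    out$flag_logistic <- la$flag
  }
  out
}
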