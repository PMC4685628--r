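# Synthetic case-control cohorts with HWE genotypes, LD blocks and planted
# two-locus epistasis. The generator is the truth set for every downstream
# stage; its defaults mirror the smaller of the two study cohorts the
# package is shaped around (49 cases vs 109 controls).

#' Simulation configuration
#'
#' Collects every knob of the cohort generator, validated once. Defaults
#' describe a small unbalanced case-control cohort (49 cases, 109
#' controls) with 1,000 biallelic SNPs in 10-SNP LD blocks.
#'
#' @param n_cases,n_controls cohort sizes (default 49 / 109).
#' @param n_snps number of biallelic variants.
#' @param block_size variants per LD block (1 = independent SNPs).
#' @param within_block_r2 target genotype r-squared between adjacent
#'   variants of a block, in `[0, 1)`.
#' @param maf_range interval in `(0, 0.5]` from which per-block MAFs are
#'   drawn uniformly.
#' @param missing_rate probability that any genotype call is missing
#'   (missing completely at random), in `[0, 1)`.
#' @param planted list of planted epistatic pairs, each a list with
#'   integer `snp1`, `snp2` (variant indices) and `model`
#'   (a [make_penetrance_model()] object). Planted loci are simulated as
#'   independent single-SNP blocks at the model's MAFs.
#' @param background_rate disease probability contributed by everything
#'   not modelled, combined with planted penetrances by a noisy-OR.
#'   Default `NULL`: 0 when pairs are planted (their baselines carry the
#'   background), 0.1 otherwise (so a null cohort still has cases).
#' @param sex_ratio probability a sample is female.
#' @param age_mean,age_sd Gaussian age distribution (years).
#' @param seed integer seed governing every random draw.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 49L, n_controls = 109L, n_snps = 1000L,
                       block_size = 10L, within_block_r2 = 0.8,
                       maf_range = c(0.05, 0.5), missing_rate = 0,
                       planted = list(), background_rate = NULL,
                       sex_ratio = 0.5, age_mean = 50, age_sd = 12,
                       seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_snps >= 1L, block_size >= 1L,
            within_block_r2 >= 0, within_block_r2 < 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            sex_ratio >= 0, sex_ratio <= 1, age_sd >= 0)
  idx <- unlist(lapply(planted, function(p) c(p$snp1, p$snp2)))
  if (length(idx)) {
    if (any(idx < 1L | idx > n_snps)) stop("planted index out of range")
    if (anyDuplicated(idx)) stop("planted indices must be distinct")
    ok <- vapply(planted, function(p) inherits(p$model, "penetrance_model"),
                 TRUE)
    if (!all(ok)) stop("each planted entry needs a penetrance_model")
  }
  if (is.null(background_rate))
    background_rate <- if (length(planted)) 0 else 0.1
  stopifnot(background_rate >= 0, background_rate < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps),
                 block_size = as.integer(block_size),
                 within_block_r2 = within_block_r2,
                 maf_range = maf_range, missing_rate = missing_rate,
                 planted = planted, background_rate = background_rate,
                 sex_ratio = sex_ratio, age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Block layout: consecutive runs of block_size, with planted loci carved
# out as singleton blocks so their MAF is the model's own.
block_layout <- function(config) {
  planted_idx <- integer(0)
  planted_maf <- numeric(0)
  for (p in config$planted) {
    planted_idx <- c(planted_idx, p$snp1, p$snp2)
    planted_maf <- c(planted_maf, p$model$maf1, p$model$maf2)
  }
  block <- integer(config$n_snps)
  b <- 0L
  fill <- 0L
  for (j in seq_len(config$n_snps)) {
    if (j %in% planted_idx || fill == 0L || fill >= config$block_size ||
        (j > 1L && (block[j - 1L] == 0L || (j - 1L) %in% planted_idx))) {
      b <- b + 1L
      fill <- 0L
    }
    if (j %in% planted_idx) {
      block[j] <- b
      fill <- config$block_size  # force a fresh block after a planted locus
    } else {
      block[j] <- b
      fill <- fill + 1L
    }
  }
  list(block = block, planted_idx = planted_idx, planted_maf = planted_maf)
}

# Draw an n x length(cols) genotype matrix for the variants `cols`
# (must form whole chains within their blocks), given per-variant MAF and
# block ids. Adjacent variants in a block are copy-with-mutation allele
# chains: each allele of variant j copies variant j-1's allele and is
# replaced by a fresh HWE draw with probability 1 - sqrt(r2), giving
# adjacent genotype correlation sqrt(r2), i.e. r-squared ~ r2.
draw_genotypes <- function(n, maf, block, r2) {
  m <- length(maf)
  mut <- 1 - sqrt(r2)
  a1 <- matrix(0L, n, m)
  a2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    if (j == 1L || block[j] != block[j - 1L]) {
      a1[, j] <- rbinom(n, 1L, maf[j])
      a2[, j] <- rbinom(n, 1L, maf[j])
    } else {
      flip1 <- rbinom(n, 1L, mut) == 1L
      flip2 <- rbinom(n, 1L, mut) == 1L
      a1[, j] <- ifelse(flip1, rbinom(n, 1L, maf[j]), a1[, j - 1L])
      a2[, j] <- ifelse(flip2, rbinom(n, 1L, maf[j]), a2[, j - 1L])
    }
  }
  a1 + a2
}

#' Simulate a case-control cohort with planted epistasis
#'
#' Generates HWE genotypes in LD blocks, assigns disease status from the
#' planted penetrance models (noisy-OR combination of pairs plus the
#' background rate), and ascertains exactly `n_cases` cases and
#' `n_controls` controls by rejection sampling from a latent population
#' (capped at one million draws). Genotypes at unplanted loci are
#' independent of status and are therefore drawn only for the retained
#' samples; planted loci are drawn for every latent individual.
#'
#' @param config a [sim_config()].
#' @return a list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (class `truth_record`: planted pairs with ids and models, per-sample
#'   latent disease probability, per-variant generating MAF).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lay <- block_layout(config)
    n_blocks <- max(lay$block)
    block_maf <- runif(n_blocks, config$maf_range[1], config$maf_range[2])
    maf <- block_maf[lay$block]
    maf[lay$planted_idx] <- lay$planted_maf

    n_need <- config$n_cases + config$n_controls
    cap <- 1e6
    batch <- max(1000L, 4L * n_need)
    kept_g_planted <- NULL
    kept_prob <- numeric(0)
    kept_status <- integer(0)
    got_cases <- 0L; got_controls <- 0L
    drawn <- 0
    pi_all <- lay$planted_idx
    while ((got_cases < config$n_cases || got_controls < config$n_controls)
           && drawn < cap) {
      nb <- as.integer(min(batch, cap - drawn))
      drawn <- drawn + nb
      gp <- if (length(pi_all))
        draw_genotypes(nb, maf[pi_all], seq_along(pi_all), 0)
      else matrix(integer(0), nb, 0L)
      prob <- rep(1 - config$background_rate, nb)
      for (k in seq_along(config$planted)) {
        pk <- config$planted[[k]]
        g1 <- gp[, match(pk$snp1, pi_all)]
        g2 <- gp[, match(pk$snp2, pi_all)]
        pen <- pk$model$table[cbind(g1 + 1L, g2 + 1L)]
        prob <- prob * (1 - pen)
      }
      prob <- 1 - prob
      st <- rbinom(nb, 1L, prob)
      # select in draw order up to each quota
      take_case <- which(st == 1L)
      take_case <- take_case[seq_len(min(length(take_case),
                                         config$n_cases - got_cases))]
      take_ctrl <- which(st == 0L)
      take_ctrl <- take_ctrl[seq_len(min(length(take_ctrl),
                                         config$n_controls - got_controls))]
      take <- sort(c(take_case, take_ctrl))
      if (length(take)) {
        kept_g_planted <- rbind(kept_g_planted,
                                gp[take, , drop = FALSE])
        kept_prob <- c(kept_prob, prob[take])
        kept_status <- c(kept_status, st[take])
        got_cases <- got_cases + length(take_case)
        got_controls <- got_controls + length(take_ctrl)
      }
    }
    if (got_cases < config$n_cases || got_controls < config$n_controls)
      stop("could not ascertain ", config$n_cases, " cases / ",
           config$n_controls, " controls within ", format(cap, scientific = FALSE),
           " latent draws; penetrance/background too extreme")

    # order: cases first, then controls, in draw order
    ord <- order(-kept_status)
    kept_status <- kept_status[ord]
    kept_prob <- kept_prob[ord]
    if (length(pi_all))
      kept_g_planted <- kept_g_planted[ord, , drop = FALSE]

    n <- n_need
    g <- matrix(NA_integer_, n, config$n_snps)
    other <- setdiff(seq_len(config$n_snps), pi_all)
    if (length(other))
      g[, other] <- draw_genotypes(n, maf[other], lay$block[other],
                                   config$within_block_r2)
    if (length(pi_all)) g[, pi_all] <- kept_g_planted

    sex <- ifelse(rbinom(n, 1L, config$sex_ratio) == 1L, "female", "male")
    age <- round(rnorm(n, config$age_mean, config$age_sd), 1)

    if (config$missing_rate > 0) {
      mask <- matrix(runif(n * config$n_snps) < config$missing_rate,
                     n, config$n_snps)
      g[mask] <- NA_integer_
    }

    vid <- sprintf("snp%05d", seq_len(config$n_snps))
    variants <- data.frame(
      id = vid, chrom = "1", pos = 5000L * seq_len(config$n_snps),
      allele_a = "A", allele_b = "B",
      gene = sprintf("GENE%04d", lay$block), stringsAsFactors = FALSE)
    samples <- data.frame(
      id = sprintf("S%04d", seq_len(n)), sex = sex, age = age,
      status = ifelse(kept_status == 1L, "case", "control"),
      stringsAsFactors = FALSE)
    ds <- genotype_dataset(g, variants, samples)

    planted_tab <- lapply(config$planted, function(p)
      list(snp1 = p$snp1, snp2 = p$snp2,
           id1 = vid[p$snp1], id2 = vid[p$snp2], model = p$model))
    truth <- structure(list(planted = planted_tab,
                            disease_prob = kept_prob,
                            true_maf = maf),
                       class = "truth_record")
    list(dataset = ds, truth = truth)
  })
}

#' Set genotypes missing completely at random
#'
#' Each genotype call is independently replaced by `NA` with probability
#' `rate`. `rate = 0` returns the dataset unchanged.
#'
#' @param ds a [genotype_dataset()].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the masked `genotype_dataset`.
#' @export
inject_missingness <- function(ds, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(ds)
  with_seed(seed, {
    g <- ds$genotypes
    mask <- matrix(runif(length(g)) < rate, nrow(g), ncol(g))
    g[mask] <- NA_integer_
    genotype_dataset(g, ds$variants, ds$samples)
  })
}

#' Write a truth record as TSV
#'
#' One row per planted pair: variant indices and ids, model kind, MAFs and
#' the 3x3 penetrance table flattened row-major into nine columns
#' `p00..p22`.
#'
#' @param truth a `truth_record` from [simulate_cohort()].
#' @param path output file.
#' @export
write_truth_record <- function(truth, path) {
  rows <- lapply(truth$planted, function(p) {
    tabs <- as.vector(t(p$model$table))
    names(tabs) <- sprintf("p%d%d", rep(0:2, each = 3), rep(0:2, 3))
    c(list(snp1 = p$snp1, snp2 = p$snp2, id1 = p$id1, id2 = p$id2,
           kind = p$model$kind, maf1 = p$model$maf1, maf2 = p$model$maf2),
      as.list(tabs))
  })
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(snp1 = integer(), snp2 = integer(),
                           id1 = character(), id2 = character(),
                           kind = character(), maf1 = numeric(),
                           maf2 = numeric())
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
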