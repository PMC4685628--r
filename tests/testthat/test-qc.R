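# Quality control: per-sample stats, HWE exact test, duplicates, PCA,
# and the full cascade.

test_that("sample stats count missingness and heterozygosity directly", {
  ds <- make_ds(rbind(c(0L, 1L, 2L, NA),
                      c(0L, 0L, 2L, 2L),
                      c(NA, NA, NA, NA)),
                c("case", "control", "control"))
  ss <- sample_stats(ds)
  expect_equal(ss$missing_rate, c(0.25, 0, 1))
  expect_equal(ss$het_rate[1], 1 / 3)
  expect_equal(ss$het_rate[2], 0)
  expect_true(is.nan(ss$het_rate[3]))

  one <- make_ds(matrix(c(1L, 0L), 2, 1), c("case", "control"))
  expect_true(all(sample_stats(one)$het_rate %in% c(0, 1)))
})

test_that("HWE exact test: conventions, symmetry and oracle spot checks", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  # allele-label symmetry on a sweep of small tables
  for (a in 0:6) for (h in 0:6) for (b in 0:a)
    expect_identical(hwe_exact_test(a, h, b), hwe_exact_test(b, h, a))
  # random larger tables against the enumeration oracle
  set.seed(31)
  for (k in 1:200) {
    cnt <- as.vector(rmultinom(1, sample(10:300, 1), c(0.3, 0.5, 0.2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("duplicate detection measures mean IBS correctly", {
  g <- rbind(c(0L, 1L, 2L, 1L),
             c(0L, 1L, 2L, 1L),   # duplicate of sample 1
             c(2L, 2L, 2L, 2L),
             c(0L, 0L, 0L, 0L))   # opposite homozygote of sample 3
  ds <- make_ds(g, rep("control", 4))
  res <- detect_duplicates(ds, 0.95)
  expect_equal(nrow(res$duplicates), 1)
  expect_equal(res$duplicates$ibs, 1.0)
  expect_equal(res$duplicates$remove, "s002")
  # full-similarity matrix path: s003 vs s004 has IBS 0
  all_pairs <- detect_duplicates(ds, 0)$duplicates
  s34 <- all_pairs[all_pairs$id1 == "s003" & all_pairs$id2 == "s004", ]
  expect_equal(s34$ibs, 0)

  # independent HWE samples at MAF 0.5: E[IBS] = 0.625
  set.seed(7)
  sims <- replicate(200, {
    gg <- matrix(rbinom(2 * 500, 2L, 0.5), 2, 500, byrow = TRUE)
    detect_duplicates(make_ds(t(gg), rep("control", 2)), 0)$duplicates$ibs
  })
  expect_lt(abs(mean(sims) - 0.625), 3 * sd(sims) / sqrt(200))

  # zero co-observed variants -> reported as undefined
  gna <- rbind(c(0L, NA), c(NA, 2L))
  und <- detect_duplicates(make_ds(gna, rep("control", 2)), 0.9)$undefined
  expect_equal(nrow(und), 1)
})

test_that("genotype PCA separates subpopulations and is scale-stable", {
  set.seed(5)
  n1 <- 60; n2 <- 60; m <- 300
  maf1 <- runif(m, 0.1, 0.3)
  maf2 <- pmin(0.5, maf1 + 0.2)
  g <- rbind(matrix(rbinom(n1 * m, 2, rep(maf1, each = n1)), n1, m),
             matrix(rbinom(n2 * m, 2, rep(maf2, each = n2)), n2, m))
  ds <- make_ds(g, rep("control", n1 + n2))
  pca <- suppressWarnings(genotype_pca(ds, k = 2))
  grp <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pca$scores[, 1], grp)), 0.9)

  # duplicating every column preserves score directions (up to scale/sign)
  ds2 <- make_ds(cbind(g, g), rep("control", n1 + n2))
  pca2 <- suppressWarnings(genotype_pca(ds2, k = 2))
  for (j in 1:2)
    expect_gt(abs(cor(pca$scores[, j], pca2$scores[, j])), 1 - 1e-6)
})

test_that("homogeneous cohorts rarely show 6-SD PCA outliers", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n_cases = 40, n_controls = 60,
                                      n_snps = 150, block_size = 1,
                                      seed = 100 + s))
    any(suppressWarnings(genotype_pca(sim$dataset))$outlier)
  }, TRUE)
  expect_lte(sum(hits), 1)   # >= 95% of seeds clean
})

test_that("the QC cascade removes exactly the planted violations", {
  res <- apply_qc(make_qc_fixture())
  rep <- res$report
  removed_samples <- rep$samples[rep$samples$removed, ]
  expect_equal(removed_samples$id, c("s001", "s002", "s004"))
  expect_equal(removed_samples$reason,
               c("sample_missing", "het_outlier", "duplicate"))
  removed_variants <- rep$variants[rep$variants$removed, ]
  expect_equal(removed_variants$id, c("v001", "v002", "v003"))
  expect_equal(removed_variants$reason,
               c("variant_missing", "low_maf", "hwe_fail"))
  # bookkeeping: removed + retained = input on both axes
  expect_equal(rep$counts$samples_out + sum(rep$samples$removed),
               rep$counts$samples_in)
  expect_equal(rep$counts$variants_out + sum(rep$variants$removed),
               rep$counts$variants_in)
  # retained variants satisfy the thresholds
  kept <- variant_stats(res$dataset)
  expect_true(all(kept$maf >= 0.01))
  expect_true(all(kept$hwe_p_controls >= 1e-5))
  expect_true(all(kept$missing_rate <= 0.05))
})

test_that("no-op thresholds are the identity and the cascade is idempotent", {
  sim <- simulate_cohort(sim_config(n_cases = 30, n_controls = 50,
                                    n_snps = 60, block_size = 3,
                                    missing_rate = 0.01, seed = 9))
  loose <- qc_thresholds(sample_missing_max = 1, het_sd_mult = Inf,
                         dup_ibs_min = 1, pca_sd_mult = Inf,
                         variant_missing_max = 1, maf_min = 0,
                         hwe_p_min = 0)
  res <- apply_qc(sim$dataset, loose)
  expect_identical(res$dataset$genotypes, sim$dataset$genotypes)
  expect_equal(res$report$counts$samples_out, 80)

  # idempotence with the heterozygosity filter disabled
  th <- qc_thresholds(het_sd_mult = Inf)
  once <- apply_qc(sim$dataset, th)
  twice <- apply_qc(once$dataset, th)
  expect_identical(twice$dataset$genotypes, once$dataset$genotypes)
  expect_false(any(twice$report$samples$removed))
  expect_false(any(twice$report$variants$removed))
})
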