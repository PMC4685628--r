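# Single-SNP association: allele tables, odds ratios, chi-square,
# logistic model, BH adjustment and genomic control.

test_that("allele tables count minor alleles by status", {
  ds <- make_ds(rbind(0L, 1L, 2L, 0L, NA),
                c("case", "case", "case", "control", "control"))
  at <- allele_table(ds, 1)
  expect_equal(at$freq_cases, 0.5)        # 3 of 6 alleles
  expect_equal(at$freq_controls, 0)
  expect_equal(sum(at$counts), 8)

  # swapping alleles maps freq -> 1 - freq and OR -> 1/OR
  ds2 <- make_ds(rbind(0L, 1L, 2L, 0L, 1L),
                 c("case", "case", "case", "control", "control"))
  at2 <- allele_table(ds2, 1)
  at2s <- allele_table(swap_alleles(ds2), 1)
  expect_equal(at2s$freq_cases, 1 - at2$freq_cases)
  o <- odds_ratio(at2$freq_cases, at2$freq_controls)
  os <- odds_ratio(at2s$freq_cases, at2s$freq_controls)
  expect_equal(os, 1 / o)

  # a group with no genotyped samples is an error
  ds3 <- make_ds(rbind(0L, NA), c("case", "control"))
  expect_error(allele_table(ds3, 1), "controls")
})

test_that("odds ratio forms agree and reproduce known identities", {
  expect_equal(odds_ratio(0.3, 0.3), 1.0)
  expect_error(odds_ratio(0, 0.5), "strictly")
  # frequency and count forms agree when frequencies come from counts
  a <- 13; b <- 87; c <- 22; d <- 78
  oc <- odds_ratio_counts(a, b, c, d)
  expect_equal(oc$or, odds_ratio(a / (a + b), c / (c + d)))
  expect_true(oc$ci_lo < oc$or && oc$or < oc$ci_hi)
  # zero cell: undefined CI unless corrected
  z <- odds_ratio_counts(0, 100, 5, 95)
  expect_true(is.na(z$ci_lo))
  zc <- odds_ratio_counts(0, 100, 5, 95, correction = TRUE)
  expect_false(is.na(zc$ci_lo))
})

test_that("allelic chi-square matches the hand-computed expectation table", {
  # identical groups: no signal
  t0 <- allelic_test(matrix(c(10, 90, 10, 90), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # (30,70 | 10,90): sum (O-E)^2/E = 12.5
  t1 <- allelic_test(matrix(c(30, 70, 10, 90), 2))
  expect_equal(t1$statistic, 12.5)
  expect_equal(t1$p, 4.07e-4, tolerance = 1e-3)
  # independent cross-check against the standard implementation
  m <- matrix(c(23, 41, 17, 55), 2)
  expect_equal(allelic_test(m)$statistic,
               unname(suppressWarnings(
                 chisq.test(m, correct = FALSE))$statistic))
  # transposing (swapping rows and columns together) changes nothing
  expect_equal(allelic_test(t(m))$statistic, allelic_test(m)$statistic)
  # zero margin convention
  expect_equal(allelic_test(matrix(c(0, 5, 0, 9), 2))$p, 1)
})

test_that("allelic test holds its type-I error at alpha = 0.05", {
  set.seed(41)
  a <- rbinom(1e4, 260, 0.3)
  c2 <- rbinom(1e4, 260, 0.3)
  rej <- mapply(function(a, c2)
    allelic_test(matrix(c(a, 260 - a, c2, 260 - c2), 2))$p < 0.05, a, c2)
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("logistic association is calibrated and agrees with the allelic test", {
  sim <- simulate_cohort(sim_config(n_cases = 100, n_controls = 160,
                                    n_snps = 600, block_size = 1,
                                    seed = 42))
  la <- logistic_assoc(sim$dataset)
  ks <- suppressWarnings(stats::ks.test(la$p[la$flag == "ok"], "punif"))
  expect_gt(ks$p.value, 0.01)

  # large balanced cohort, no covariates: p-values track the allelic test
  sim2 <- simulate_cohort(sim_config(n_cases = 400, n_controls = 400,
                                     n_snps = 120, block_size = 1,
                                     seed = 7))
  as2 <- single_snp_association(sim2$dataset)
  la2 <- logistic_assoc(sim2$dataset, covariates = character(0))
  expect_gt(cor(as2$p_nominal, la2$p, method = "spearman",
                use = "complete.obs"), 0.95)

  # constant genotype is flagged, not fitted
  dsc <- make_ds(cbind(rep(1L, 40), rbinom(40, 2, 0.3)),
                 rep(c("case", "control"), 20))
  lc <- logistic_assoc(dsc, covariates = character(0))
  expect_equal(lc$flag[1], "constant")
  expect_true(is.na(lc$p[1]))
})

test_that("BH adjustment follows the step-up rule and is order-equivariant", {
  expect_equal(bh_adjust(0.57), 0.57)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")

  set.seed(13)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  # adjusted values are monotone in the nominal ranking
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
})

test_that("genomic-control lambda is calibrated and monotone", {
  m <- 1001  # odd, so the median of the grid is exactly 0.5
  grid <- (seq_len(m) - 0.5) / m
  out <- qq_lambda(grid)
  expect_equal(out$lambda_gc, 1.0, tolerance = 1e-6)
  expect_equal(out$qq$expected, sort(out$qq$expected, decreasing = TRUE))
  # deflating every p inflates lambda
  expect_gt(qq_lambda(grid * 0.1)$lambda_gc, out$lambda_gc)
  expect_error(qq_lambda(rep(0.5, 5)), "at least 10")
  # manhattan coordinates are cumulative across chromosomes
  v <- data.frame(chrom = rep(c("1", "2"), c(500, 501)),
                  pos = c(seq_len(500), seq_len(501)))
  man <- qq_lambda(grid, v)$manhattan
  expect_true(all(diff(man$cum_pos) > 0))
})
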