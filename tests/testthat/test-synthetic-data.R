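# Cohort generator: penetrance models, ascertainment, LD structure,
# missingness and determinism.

test_that("penetrance model kinds produce the defining tables", {
  m0 <- make_penetrance_model("null", 0.1, effect = 0.7)
  expect_true(all(m0$table == 0.1))

  mx <- make_penetrance_model("xor", 0.05, 0.45)
  odd <- (matrix(0:2, 3, 3) + t(matrix(0:2, 3, 3))) %% 2 == 1
  expect_true(all(mx$table[odd] == 0.5))
  expect_true(all(mx$table[!odd] == 0.05))

  # multiplicative: factor per locus carrying a minor allele
  mm <- make_penetrance_model("multiplicative", 0.05, 2.0)
  expect_equal(mm$table[3, 3], min(1, 0.05 * 2 * 2))
  expect_equal(mm$table[1, 1], 0.05)
  expect_equal(mm$table[1, 3], 0.1)

  expect_error(make_penetrance_model("frobnicate", 0.1), "invalid")
  expect_error(make_penetrance_model("null", 1.2), "baseline")
  expect_error(make_penetrance_model("xor", 0.8, 0.45), "out of range")
})

test_that("simulation is reproducible and respects cohort shape", {
  cfg <- sim_config(n_cases = 30, n_controls = 70, n_snps = 50,
                    block_size = 5, missing_rate = 0.02, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dataset$genotypes, b$dataset$genotypes)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$truth$true_maf, b$truth$true_maf)
  expect_equal(sum(a$dataset$samples$status == "case"), 30)
  expect_equal(sum(a$dataset$samples$status == "control"), 70)
})

test_that("null cohorts carry no genotype-phenotype signal", {
  sim <- simulate_cohort(sim_config(n_cases = 100, n_controls = 160,
                                    n_snps = 1000, block_size = 1,
                                    seed = 42))
  as <- single_snp_association(sim$dataset)
  ks <- suppressWarnings(stats::ks.test(as$p_nominal, "punif"))
  expect_gt(ks$p.value, 0.01)
  # case fraction per genotype cell of an arbitrary pair ~ background rate
  g <- sim$dataset$genotypes
  s01 <- as.integer(sim$dataset$samples$status == "case")
  cells <- paste(g[, 1], g[, 2])
  big <- names(which(table(cells) >= 20))
  frac <- tapply(s01, cells, mean)[big]
  expect_true(all(abs(frac - mean(s01)) < 0.25))
})

test_that("empirical MAF tracks the generating MAF", {
  sim <- simulate_cohort(sim_config(n_cases = 100, n_controls = 150,
                                    n_snps = 400, block_size = 4, seed = 8))
  emp <- variant_maf(sim$dataset)
  tru <- sim$truth$true_maf
  se <- sqrt(tru * (1 - tru) / (2 * 250))
  frac_in <- mean(abs(emp - tru) <= 3 * se)
  expect_gt(frac_in, 0.985)   # 3*SE covers ~99.7% per variant
})

test_that("LD blocks hit the target adjacent r2 and planted pairs shape risk", {
  sim <- simulate_cohort(sim_config(n_cases = 150, n_controls = 150,
                                    n_snps = 300, block_size = 10,
                                    within_block_r2 = 0.8, seed = 13))
  g <- sim$dataset$genotypes
  blocks <- sim$dataset$variants$gene
  adj <- which(blocks[-1] == blocks[-length(blocks)])
  r2 <- vapply(adj, function(j) genotype_r2(g[, j], g[, j + 1]), 0)
  expect_gt(length(r2), 100)
  expect_lt(abs(mean(r2, na.rm = TRUE) - 0.8), 0.15)

  # xor pair: case fraction higher in odd-sum cells than even-sum cells
  m <- make_penetrance_model("xor", 0.05, 0.45, 0.3, 0.3)
  sim2 <- simulate_cohort(sim_config(
    n_cases = 100, n_controls = 100, n_snps = 10, block_size = 1,
    planted = list(list(snp1 = 3L, snp2 = 7L, model = m)), seed = 21))
  g1 <- sim2$dataset$genotypes[, 3]
  g2 <- sim2$dataset$genotypes[, 7]
  s01 <- as.integer(sim2$dataset$samples$status == "case")
  odd <- (g1 + g2) %% 2 == 1
  expect_gt(mean(s01[odd]), mean(s01[!odd]))
})

test_that("unattainable case quotas fail loudly", {
  m <- make_penetrance_model("null", 0)  # nobody can ever be a case
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_snps = 2, block_size = 1,
                    planted = list(list(snp1 = 1L, snp2 = 2L, model = m)),
                    background_rate = 0, seed = 1)
  expect_error(simulate_cohort(cfg), "ascertain")
})

test_that("missingness injection is MCAR at the requested rate", {
  sim <- simulate_cohort(sim_config(n_cases = 40, n_controls = 60,
                                    n_snps = 1000, block_size = 1, seed = 3))
  expect_identical(inject_missingness(sim$dataset, 0), sim$dataset)
  expect_error(inject_missingness(sim$dataset, 1), "rate")

  masked <- inject_missingness(sim$dataset, 0.05, seed = 17)
  n_miss <- sum(is.na(masked$genotypes))
  bounds <- qbinom(c(0.005, 0.995), 100 * 1000, 0.05)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])

  # heavy missingness forces every sample over the 7% threshold
  heavy <- inject_missingness(sim$dataset, 0.5, seed = 18)
  expect_true(all(sample_stats(heavy)$missing_rate > 0.07))
})
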