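# The MDR engine: folds, risk grids, pair evaluation, the exhaustive
# scan and permutation nulls.

test_that("stratified folds balance both classes and are reproducible", {
  status <- rep(c("case", "control"), c(49, 109))
  f <- make_folds(status, 10, seed = 3)
  case_counts <- table(f[status == "case"])
  ctrl_counts <- table(f[status == "control"])
  expect_true(all(case_counts %in% 4:5))
  expect_true(all(ctrl_counts %in% 10:11))
  expect_identical(f, make_folds(status, 10, seed = 3))
  expect_false(identical(f, make_folds(status, 10, seed = 4)))

  # leave-one-out with 1:1 classes: every fold holds exactly one sample
  loo <- make_folds(rep(c("case", "control"), 5), 10, seed = 1)
  expect_equal(sort(as.integer(table(loo))), rep(1L, 10))
  expect_error(make_folds(rep("case", 3), 5), "folds")
})

test_that("risk grids label cells by the case:control ratio", {
  g1 <- c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, NA)
  g2 <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  st <- c("case", "case", "case", "control", "case", "case",
          "control", "control", "case")
  grid <- fit_risk_grid(g1, g2, st, T = 1)
  expect_equal(grid$label[1, 1], "high")    # 3 cases / 1 control
  expect_equal(grid$label[2, 1], "high")    # 2 cases / 0 controls
  expect_equal(grid$label[3, 1], "low")     # 0 cases / 2 controls
  expect_equal(grid$label[1, 2], "empty")
  expect_equal(sum(grid$cases) + sum(grid$controls), 8)  # NA excluded
})

test_that("a perfectly separating pair scores CVV 1 and permutes to p = 1/200", {
  ds <- make_separating_ds()
  cfg <- mdr_config(seed = 5)
  mod <- evaluate_pair(ds, c("v001", "v002"), cfg)
  expect_equal(mod$cvv, 1.0)
  expect_true(mod$significant)
  pn <- permutation_null(ds, c("v001", "v002"), n_perm = 199,
                         config = cfg, seed = 11)
  expect_equal(pn$p, 1 / 200)
})

test_that("evaluate_pair matches the naive oracle on random micro-instances", {
  set.seed(55)
  for (k in 1:15) {
    n <- sample(12:20, 1)
    n_case <- sample(4:(n - 4), 1)
    status <- sample(rep(c("case", "control"), c(n_case, n - n_case)))
    g <- matrix(sample(c(0:2, NA), n * 2, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), n, 2)
    ds <- make_ds(g, status)
    policy <- sample(c("low_risk", "unknown_misclassified"), 1)
    cfg <- mdr_config(n_folds = sample(2:5, 1),
                      empty_cell_policy = policy, seed = k)
    mod <- evaluate_pair(ds, c(1L, 2L), cfg)
    oracle <- oracle_mdr_cvv(g, as.integer(status == "case"), mod$folds,
                             1, 2, policy = policy)
    expect_equal(mod$cvv, oracle, tolerance = 1e-12)
  }
})

test_that("the compiled scan agrees with evaluate_pair and is ranked", {
  sim <- simulate_cohort(sim_config(n_cases = 40, n_controls = 80,
                                    n_snps = 15, block_size = 1,
                                    missing_rate = 0.02, seed = 77))
  cfg <- mdr_config(seed = 9)
  sc <- scan_pairs(sim$dataset, NULL, cfg)
  expect_equal(nrow(sc), choose(15, 2))
  expect_true(all(diff(sc$cvv) <= 0))
  for (k in c(1, 25, 60, 105)) {
    mod <- evaluate_pair(sim$dataset, c(sc$id1[k], sc$id2[k]), cfg)
    expect_identical(mod$cvv, sc$cvv[k])
  }
  # both empty-cell policies agree between the two implementations
  cfg2 <- mdr_config(seed = 9, empty_cell_policy = "unknown_misclassified")
  sc2 <- scan_pairs(sim$dataset, NULL, cfg2)
  mod2 <- evaluate_pair(sim$dataset, c(sc2$id1[1], sc2$id2[1]), cfg2)
  expect_identical(mod2$cvv, sc2$cvv[1])

  # a universe of one pair reduces to evaluate_pair
  one <- scan_pairs(sim$dataset, matrix(c(3L, 9L), 1), cfg)
  expect_identical(one$cvv,
                   evaluate_pair(sim$dataset, c(3L, 9L), cfg)$cvv)
})

test_that("scan results are invariant to worker count", {
  sim <- simulate_cohort(sim_config(n_cases = 30, n_controls = 60,
                                    n_snps = 25, block_size = 1, seed = 6))
  cfg <- mdr_config(seed = 2)
  s1 <- scan_pairs(sim$dataset, NULL, cfg, workers = 1)
  s4 <- scan_pairs(sim$dataset, NULL, cfg, workers = 4)
  expect_identical(s1, s4)
})

test_that("relabelling case<->control inverts risk labels consistently", {
  sim <- simulate_cohort(sim_config(n_cases = 50, n_controls = 50,
                                    n_snps = 4, block_size = 1, seed = 12))
  ds <- sim$dataset
  g1 <- ds$genotypes[, 1]; g2 <- ds$genotypes[, 2]
  grid <- fit_risk_grid(g1, g2, ds$samples$status, T = 1)
  flipped <- fit_risk_grid(g1, g2,
                           ifelse(ds$samples$status == "case",
                                  "control", "case"), T = 1)
  # with a 1:1 threshold, counts swap roles exactly
  expect_identical(grid$cases, flipped$controls)
  expect_identical(grid$controls, flipped$cases)
})

test_that("significance filtering uses a strict threshold", {
  models <- data.frame(id1 = c("a", "b", "c"), id2 = c("x", "y", "z"),
                       cvv = c(0.709, 0.548, 0.500))
  kept <- significance_filter(models, 0.5)
  expect_equal(kept$cvv, c(0.709, 0.548))
})

test_that("per-pair permutation p is uniform for a null pair", {
  ps <- vapply(1:60, function(r) {
    sim <- simulate_cohort(sim_config(n_cases = 50, n_controls = 50,
                                      n_snps = 2, block_size = 1,
                                      seed = 3000 + r))
    permutation_null(sim$dataset, c(1L, 2L), n_perm = 100,
                     config = mdr_config(seed = r), seed = 7000 + r)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(permutation_null(make_separating_ds(), c(1L, 2L),
                                n_perm = 50), "n_perm")
})
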