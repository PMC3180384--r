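test_that("gamma matches hand evaluations of the defining formula", {
  # g2 = 1, g3 = 2/3: T_2 = 2 = T/2, so gamma = 0 by symmetry
  expect_equal(gamma_statistic(bt_from_intervals(c(1, 2 / 3)))$gamma, 0,
               tolerance = 1e-12)
  # g2 = 1, g3 = 1: (2 - 2.5) / (5 sqrt(1/12))
  expect_equal(gamma_statistic(bt_from_intervals(c(1, 1)))$gamma,
               -0.5 / (5 * sqrt(1 / 12)), tolerance = 1e-12)
  expect_equal(gamma_statistic(bt_from_intervals(c(1, 1)))$gamma,
               -0.3464102, tolerance = 1e-6)
  # late-interval compression gives positive gamma
  expect_equal(gamma_statistic(bt_from_intervals(c(1, 0.1)))$gamma,
               1.280211, tolerance = 1e-6)
})

test_that("gamma agrees with the ape oracle on simulated trees", {
  set.seed(3)
  for (i in 1:20) {
    tr <- simulate_tree("yule", sample(4:60, 1))
    expect_equal(gamma_statistic(tr)$gamma, gamma_oracle(tr),
                 tolerance = 1e-10)
  }
})

test_that("gamma is invariant under rescaling of branch lengths", {
  set.seed(5)
  for (c_scale in c(0.01, 3, 1000)) {
    tr <- simulate_tree("yule", 25)
    sc <- tr
    sc$edge.length <- sc$edge.length * c_scale
    expect_equal(gamma_statistic(sc)$gamma, gamma_statistic(tr)$gamma,
                 tolerance = 1e-9)
  }
})

test_that("the asymptotic constancy test uses the N(0,1) lower tail", {
  expect_equal(gamma_crit(0.05), -1.645, tolerance = 5e-4)
  expect_true(gamma_reject_constant(-2.0))
  expect_false(gamma_reject_constant(-1.0))
  expect_false(gamma_reject_constant(-1.644))  # just above the threshold
  expect_true(gamma_reject_constant(-1.646))   # just below it
  expect_error(gamma_crit(0), "alpha")
  expect_error(gamma_reject_constant(-1, alpha = 1.2), "alpha")
  p <- gamma_statistic(bt_from_intervals(c(1, 1)))
  expect_equal(p$p_one_tailed, pnorm(p$gamma))
})

test_that("degenerate all-zero branching times raise an error", {
  expect_error(gamma_statistic(branching_times(c(0, 0, 0))), "degenerate")
})

test_that("MCCR p-values follow the add-one Monte Carlo convention", {
  m_lo <- mccr_test(-Inf, 5, 6, reps = 50, seed = 2)
  m_hi <- mccr_test(Inf, 5, 6, reps = 50, seed = 2)
  expect_equal(m_lo$p, 1 / 51)
  expect_equal(m_hi$p, 1)
  expect_equal(m_lo$critical_value,
               unname(quantile(m_lo$null_sample, 0.05, type = 7)))
  expect_identical(m_lo$n_full, 7L)   # 6 known + 10% -> 7
  # reproducible under the same seed
  m2 <- mccr_test(-Inf, 5, 6, reps = 50, seed = 2)
  expect_identical(m_lo$null_sample, m2$null_sample)
})

test_that("MCCR critical value approaches -1.645 under complete sampling", {
  m <- mccr_test(0, 500, 500, reps = 2000, extra_fraction = 0, seed = 6)
  expect_equal(m$critical_value, qnorm(0.05), tolerance = 0.08)
})

test_that("the MCCR test is correctly sized by construction", {
  m <- mccr_test(0, 11, 13, reps = 2000, seed = 8)
  fresh <- simulate_pruned_null(11, 14, reps = 1000, seed = 5000)
  g <- vapply(fresh, function(t) gamma_statistic(t)$gamma, numeric(1))
  rate <- mean(g <= m$critical_value)
  band <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000   # 99% binomial band
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("gamma over a Yule tree sample is near-standard-normal", {
  set.seed(17)
  trees <- replicate(1000, simulate_tree("yule", 100), simplify = FALSE)
  gs <- gamma_over_sample(trees)
  expect_equal(gs$mean, 0, tolerance = 0.1)
  expect_equal(gs$sd, 1, tolerance = 0.1)
  ks <- suppressWarnings(ks.test(gs$gamma, "pnorm"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("single-tree samples report sd 0 with a warning", {
  tr <- simulate_tree("yule", 10, seed = 1)
  expect_warning(gs <- gamma_over_sample(list(tr)), "single-tree")
  expect_equal(gs$sd, 0)
  expect_equal(gs$mean, gamma_statistic(tr)$gamma)
})

test_that("LTT curves step from (root, 2) to (0, n)", {
  l <- ltt(tree3())
  expect_equal(l$age, c(2, 1, 0))
  expect_equal(l$lineages, c(2, 3, 3))
  tr <- simulate_tree("ddl", 15, r1 = 4, K = 20, seed = 4)
  l2 <- ltt(tr)
  expect_equal(l2$lineages[nrow(l2)], 15)
  expect_true(all(diff(l2$lineages) %in% c(0, 1)))
  expect_true(all(diff(l2$age) <= 0))
})

test_that("log lineage count grows linearly on a Yule tree", {
  tr <- simulate_tree("yule", 200, seed = 23)
  l <- ltt(tr)
  fwd <- max(l$age) - l$age
  r2 <- summary(lm(log(l$lineages) ~ fwd))$r.squared
  expect_gt(r2, 0.9)
})

test_that("LTT export covers multi-tree samples and CSV round-trips", {
  s <- simulate_pruned_null(5, 6, reps = 3, seed = 9)
  l <- ltt(s)
  expect_setequal(unique(l$tree), 1:3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ltt(s[[1]], f)
  back <- read.csv(f)
  expect_equal(back, ltt(s[[1]]))
})

test_that("age-size correlation reproduces the nine-clade decoupling", {
  expect_equal(pearson_age_size(c(1, 2, 3), c(10, 20, 30))$r, 1.0)
  expect_equal(pearson_age_size(c(1, 2, 3), c(30, 20, 10))$r, -1.0)
  cl <- nc_clades()
  expect_equal(round(pearson_age_size(cl$age_ma, cl$n_sampled)$r, 2), 0.22)
  expect_error(pearson_age_size(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_age_size(c(1, 2), c(1, 2)), "at least 3")
})

test_that("COI clock arithmetic is linear in divergence", {
  expect_equal(age_from_divergence(2.3), 1.0)
  expect_equal(age_from_divergence(0), 0)
  expect_equal(age_from_divergence(4.6), 2.0)
  expect_equal(age_from_divergence(2.3, rate = 1.15), 2.0)
  expect_error(age_from_divergence(1, rate = 0), "positive")
  expect_error(age_from_divergence(-1), "non-negative")
})
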