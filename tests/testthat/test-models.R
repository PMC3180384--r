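test_that("pure-birth likelihood matches a closed-form hand evaluation", {
  # n = 4, g2 = g3 = g4 = 0.5, lambda = 4/9:
  # LH = ln(2 lam) + ln(3 lam) - lam (2 + 3 + 4) * 0.5
  bt <- bt_from_intervals(c(0.5, 0.5, 0.5))
  lam <- 4 / 9
  expect_equal(model_loglik(bt, "yule1", list(lambda = lam)),
               log(2 * lam) + log(3 * lam) - lam * 4.5, tolerance = 1e-12)
  expect_equal(model_loglik(bt, "yule1", list(lambda = lam)),
               -1.830101, tolerance = 1e-6)
})

test_that("the Yule MLE has its closed form (n-2)/T", {
  bt <- bt_from_intervals(c(1, 1))
  f <- fit_model(branching_times(simulate_tree("yule", 12, seed = 2)), "yule1")
  bt12 <- branching_times(simulate_tree("yule", 12, seed = 2))
  expect_equal(f$params[["lambda"]], (bt12$n - 2) / bt12$total)
  # 3-tip closed form lambda = 1/5 (checked through the formula directly)
  expect_equal((3 - 2) / branching_times(tree3())$total, 0.2)
})

test_that("birth-death likelihood agrees with the ape oracle", {
  set.seed(9)
  for (i in 1:5) {
    tr <- ape::rphylo(sample(10:40, 1), 1, 0.5)
    f <- fit_model(tr, "bd")
    o <- suppressWarnings(ape::birthdeath(tr))
    expect_equal(-2 * f$loglik, o$dev, tolerance = 1e-4)
    expect_equal(unname(f$params["a"]), unname(o$para[1]), tolerance = 0.02)
    expect_equal(unname(f$params["r"]), unname(o$para[2]), tolerance = 0.02)
  }
})

test_that("nesting identities tie the model family together", {
  set.seed(21)
  for (i in 1:50) {
    bt <- branching_times(simulate_tree("yule", sample(5:30, 1)))
    lam <- runif(1, 0.2, 3)
    expect_equal(model_loglik(bt, "bd", list(r = lam, a = 0)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-8)
  }
  for (i in 1:10) {
    bt <- branching_times(simulate_tree("yule", 15))
    lam <- runif(1, 0.2, 3)
    expect_equal(model_loglik(bt, "ddl", list(r1 = lam, K = 1e9)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-6)
    expect_equal(model_loglik(bt, "ddx", list(r1 = lam, x = 0)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-12)
    # equal epoch rates collapse the two-rate model
    expect_equal(model_loglik(bt, "yule2",
                              list(r1 = lam, r2 = lam, st = bt$depth / 2)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-9)
    # spvar without decay is the constant birth-death model
    mu <- runif(1, 0, 0.8) * lam
    expect_equal(model_loglik(bt, "spvar", list(lambda0 = lam, k = 0, mu0 = mu)),
                 model_loglik(bt, "bd", list(r = lam - mu, a = mu / lam)),
                 tolerance = 1e-8)
    expect_equal(model_loglik(bt, "exvar", list(lambda0 = lam, mu0 = mu, z = 0)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-8)
    # z = 0 switches extinction off entirely (mu(t) = mu0 (1 - e^{-z t}))
    expect_equal(model_loglik(bt, "bothvar",
                              list(lambda0 = lam, k = 0, mu0 = mu, z = 0)),
                 model_loglik(bt, "yule1", list(lambda = lam)),
                 tolerance = 1e-8)
    # while a fast-saturating z recovers near-constant extinction
    expect_equal(model_loglik(bt, "bothvar",
                              list(lambda0 = lam, k = 0, mu0 = mu, z = 1e4)),
                 model_loglik(bt, "bd", list(r = lam - mu, a = mu / lam)),
                 tolerance = 1e-2)
  }
})

test_that("rates that are non-positive at an observed branching give -Inf", {
  bt <- branching_times(simulate_tree("yule", 10, seed = 6))
  expect_identical(model_loglik(bt, "ddl", list(r1 = 1, K = 5)), -Inf)
  expect_identical(model_loglik(bt, "bd", list(r = -1, a = 0)), -Inf)
  # K between n-1 and n: final-interval rate <= 0 but likelihood finite
  ll <- model_loglik(bt, "ddl", list(r1 = 1, K = 9.5))
  expect_true(is.finite(ll))
})

test_that("AIC identity and parameter counts hold for every fit", {
  bt <- branching_times(simulate_tree("ddl", 20, r1 = 4, K = 25, seed = 14))
  expected_k <- c(yule1 = 1L, bd = 2L, ddl = 2L, ddx = 2L, yule2 = 3L,
                  spvar = 3L, exvar = 3L, bothvar = 4L)
  for (m in names(expected_k)) {
    f <- fit_model(bt, m, restarts = 4)
    expect_identical(f$n_params, expected_k[[m]])
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params, tolerance = 1e-9)
  }
})

test_that("numerical fits match the dense grid-search oracle on small trees", {
  set.seed(33)
  for (i in 1:4) {
    n <- sample(6:8, 1)
    bt <- branching_times(simulate_tree("yule", n))
    # yule1: 1-D grid through the 2-D helper with a dummy second axis
    g <- grid_fit_oracle(bt, function(b, a, dummy)
      model_loglik(b, "yule1", list(lambda = a)), c(0.01, 0), c(30, 1))
    expect_equal(fit_model(bt, "yule1")$loglik, g$loglik, tolerance = 1e-2)
    g_ddl <- ddl_profile_oracle(bt)
    expect_equal(fit_model(bt, "ddl")$loglik, g_ddl$loglik, tolerance = 1e-2)
    g_ddx <- grid_fit_oracle(bt, function(b, r1, x)
      model_loglik(b, "ddx", list(r1 = r1, x = x)), c(0.01, -3), c(30, 5))
    expect_gte(fit_model(bt, "ddx")$loglik + 1e-2, g_ddx$loglik)
  }
})

test_that("fitted nested models never fall below what they contain", {
  set.seed(51)
  for (i in 1:5) {
    bt <- branching_times(simulate_tree("yule", 20))
    y <- fit_model(bt, "yule1")
    expect_gte(fit_model(bt, "ddl")$loglik, y$loglik - 1e-9)
    expect_gte(fit_model(bt, "bd")$loglik, y$loglik - 1e-9)
    expect_gte(fit_model(bt, "ddx")$loglik, y$loglik - 1e-9)
  }
})

test_that("two-rate Yule recovers a strong simulated shift", {
  tr <- simulate_tree("yule2", 40, r1 = 12, r2 = 1.2, st = 0.25, seed = 61)
  bt <- branching_times(scale_to_unit_depth(tr))
  f <- fit_model(bt, "yule2")
  expect_gt(f$params[["r1"]] / f$params[["r2"]], 2)
  expect_true(f$params[["st"]] > 0 && f$params[["st"]] < bt$depth)
  expect_gt(f$loglik, fit_model(bt, "yule1")$loglik)
})

test_that("extended time-varying fits honour their nesting contracts", {
  bt <- branching_times(simulate_tree("bd", 20, lambda = 1.5, mu = 0.6, seed = 71))
  bd <- fit_model(bt, "bd")
  ext <- fit_extended(bt, restarts = 4)
  # spvar contains bd at k = 0, so its fitted LH can only be higher
  expect_gte(ext$spvar$loglik, bd$loglik - 1e-6)
  expect_gte(ext$bothvar$loglik,
             max(ext$spvar$loglik, ext$exvar$loglik) - 1e-6)
})

test_that("extra time-varying parameters are penalised on Yule trees", {
  set.seed(81)
  worse <- logical(40)
  for (i in seq_along(worse)) {
    bt <- branching_times(simulate_tree("yule", 15))
    worse[i] <- fit_model(bt, "spvar", restarts = 3)$aic >
      fit_model(bt, "yule1")$aic
  }
  expect_gt(mean(worse), 0.5)
})
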