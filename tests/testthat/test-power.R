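tab1_case1 <- planning_config(beta11 = 0.5, beta12 = 0,
                              sigma2_1 = 1, sigma2_2 = 1,
                              tau2_1 = 1, tau2_2 = 1)

test_that("noncentrality, effect size and plug-in df match benchmarks", {
  # balanced unit-variance case: delta* as tabulated, df exactly 2c
  expect_4dp(expected_ncp(tab1_case1, 65, 65) / 130, 0.0218)
  expect_4dp(plugin_df(tab1_case1, 65, 65), 126)
  # strongly unbalanced case with unequal predictor variances
  expect_4dp(expected_ncp(table6_case11, 6, 18) / 24, 0.1263)
  expect_4dp(effect_size_delta_star(table6_case11, 6, 18), 0.1263)
  # plug-in df from an independent hand evaluation of the weight formula:
  # a1 = 1/20, a2 = 1/17 -> 1/nu = w1^2/4 + w2^2/16
  a1 <- 1 / 20; a2 <- 1 / 17
  nu_hand <- 1 / ((a1 / (a1 + a2))^2 / 4 + (a2 / (a1 + a2))^2 / 16)
  expect_equal(plugin_df(table6_case11, 6, 18), nu_hand, tolerance = 1e-12)
  # moderate unbalanced allocation, equal variances
  cfg2 <- planning_config(0.5, 0, 1, 1, 1, 1)
  expect_4dp(effect_size_delta_star(cfg2, 44, 132), 0.0162)
  cfg4 <- planning_config(0.75, 0, 1, 1, 4, 1)
  expect_4dp(effect_size_delta_star(cfg4, 10, 30), 0.0751)
  # zero slope difference: no signal
  null_cfg <- planning_config(0, 0, 1, 1, 1, 1)
  expect_4dp(expected_ncp(null_cfg, 20, 20), 0)
  expect_equal(effect_size_delta_star(null_cfg, 20, 20), 0)
})

test_that("simplified-t power reproduces tabulated planning values", {
  expect_4dp(power_simplified(tab1_case1, 65, 65)$power, 0.8015)
  expect_4dp(power_simplified(table6_case11, 6, 18)$power, 0.8050)
})

test_that("mixed-t power reproduces tabulated and worked-example values", {
  expect_equal(power_mixed(mice$planning, 9, 25)$power, 0.3013,
               tolerance = 5e-4)
  expect_equal(power_mixed(tab1_case1, 67, 67)$power, 0.8025,
               tolerance = 5e-4)
  expect_equal(power_mixed(table6_case11, 8, 24)$power, 0.8578,
               tolerance = 5e-4)
})

test_that("both power functions are exactly alpha under the null", {
  for (alpha in c(0.01, 0.05, 0.10)) {
    null_cfg <- planning_config(1.4, 1.4, 2, 1, 1, 3, alpha = alpha)
    expect_equal(power_simplified(null_cfg, 12, 31)$power, alpha,
                 tolerance = 1e-12)
    expect_equal(power_mixed(null_cfg, 12, 31)$power, alpha,
                 tolerance = 1e-9)
  }
})

test_that("power is monotone in effect size, sample size and noise", {
  n1 <- 15L; n2 <- 30L
  powers_b <- sapply(c(0.2, 0.4, 0.8, 1.6), function(b) {
    cfg <- planning_config(b, 0, 1, 2, 1, 1)
    c(power_simplified(cfg, n1, n2)$power, power_mixed(cfg, n1, n2)$power)
  })
  expect_true(all(diff(powers_b[1, ]) > 0))
  expect_true(all(diff(powers_b[2, ]) > 0))
  # negated difference gives the same two-sided power
  cfg_pos <- planning_config(0.8, 0, 1, 2, 1, 1)
  cfg_neg <- planning_config(0, 0.8, 1, 2, 1, 1)
  expect_equal(power_mixed(cfg_pos, n1, n2)$power,
               power_mixed(cfg_neg, n1, n2)$power, tolerance = 1e-10)

  powers_n <- sapply(c(8L, 16L, 32L, 64L), function(n) {
    cfg <- planning_config(0.8, 0, 1, 2, 1, 1)
    c(power_simplified(cfg, n, n2)$power, power_mixed(cfg, n, n2)$power)
  })
  expect_true(all(diff(powers_n[1, ]) > 0))
  expect_true(all(diff(powers_n[2, ]) > 0))

  powers_s <- sapply(c(0.5, 1, 2, 4), function(s2) {
    cfg <- planning_config(0.8, 0, s2, 2, 1, 1)
    c(power_simplified(cfg, n1, n2)$power, power_mixed(cfg, n1, n2)$power)
  })
  expect_true(all(diff(powers_s[1, ]) < 0))
  expect_true(all(diff(powers_s[2, ]) < 0))
})

test_that("power is symmetric under exchange of group labels", {
  cfg <- planning_config(1.1, 0.3, 2, 5, 3, 0.5)
  swp <- planning_config(0.3, 1.1, 5, 2, 0.5, 3)
  expect_equal(power_simplified(cfg, 9, 22)$power,
               power_simplified(swp, 22, 9)$power, tolerance = 1e-12)
  expect_equal(power_mixed(cfg, 9, 22)$power,
               power_mixed(swp, 22, 9)$power, tolerance = 1e-9)
})

test_that("quadrature matches its Monte Carlo cross-check", {
  set.seed(99)
  for (i in 1:20) {
    cfg <- planning_config(beta11 = runif(1, 0.2, 1.5), beta12 = 0,
                           sigma2_1 = runif(1, 0.5, 4),
                           sigma2_2 = runif(1, 0.5, 4),
                           tau2_1 = runif(1, 0.5, 4),
                           tau2_2 = runif(1, 0.5, 4))
    n1 <- sample(5:40, 1L); n2 <- sample(5:40, 1L)
    q <- power_mixed(cfg, n1, n2)$power
    mc <- power_mixed_mc(cfg, n1, n2, reps = 1e5)
    expect_lt(abs(q - mc$estimate), 3 * mc$mc_se + 1e-6)
  }
  # the stochastic route also sees alpha under the null
  null_cfg <- planning_config(0, 0, 1, 1, 1, 1)
  mc0 <- power_mixed_mc(null_cfg, 10, 10, reps = 1e5, seed = 1)
  expect_lt(abs(mc0$estimate - 0.05), 3 * mc0$mc_se + 1e-6)
})

test_that("simplified and mixed powers converge together as n grows", {
  gaps <- sapply(c(10L, 50L, 250L, 1250L), function(n) {
    abs(power_mixed(table6_case11, n, n)$power -
          power_simplified(table6_case11, n, n)$power)
  })
  # decreasing until both approximations saturate at floating precision
  expect_true(all(diff(gaps) < 1e-8))
  expect_lt(gaps[4L], 1e-6)
})

test_that("the mixing grid is a proper renormalized quadrature rule", {
  g <- mixing_grid(9, 25)
  expect_equal(sum(g$w1), 1)
  expect_equal(sum(g$w2), 1)
  expect_true(all(g$w1 > 0) && all(g$w2 > 0))
  expect_true(!is.unsorted(g$k1) && !is.unsorted(g$k2))
  # mean and variance of K recover the chi-square moments
  expect_equal(sum(g$w1 * g$k1), 8, tolerance = 1e-8)
  expect_equal(sum(g$w2 * g$k2), 24, tolerance = 1e-8)
  expect_equal(sum(g$w1 * g$k1^2) - 64, 16, tolerance = 1e-6)
  expect_error(power_mixed(mice$planning, 10, 25, grid = g),
               "built for sizes")
})

test_that("planning functions reject inadmissible sizes and grids", {
  expect_error(power_mixed(mice$planning, 3, 25), ">= 4")
  expect_error(power_simplified(mice$planning, 9.5, 25), ">= 4")
  expect_error(mixing_grid(9, 25, nodes = 2), "at least 4")
  expect_error(power_mixed_mc(mice$planning, 9, 25, reps = 10), "1000")
})
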