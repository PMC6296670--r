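test_that("identical seed and scenario reproduce results bit for bit", {
  a <- simulate_rejection_rate(table6_case11, 6, 18, reps = 500, seed = 7)
  b <- simulate_rejection_rate(table6_case11, 6, 18, reps = 500, seed = 7)
  expect_identical(a$rejection_rate, b$rejection_rate)
  expect_identical(a$error_mt, b$error_mt)
  c <- simulate_rejection_rate(table6_case11, 6, 18, reps = 500, seed = 8)
  expect_false(identical(a$rejection_rate, c$rejection_rate))
})

test_that("empirical power agrees with the mixed-t prediction", {
  # moderate scheme: the mixed-t approximation is the accuracy benchmark
  sim <- simulate_rejection_rate(table6_case11, 8, 24, reps = 4000,
                                 seed = 31)
  expect_lt(abs(sim$error_mt), 3 * sqrt(0.85 * 0.15 / 4000) + 0.005)
  expect_equal(sim$mc_se,
               sqrt(sim$rejection_rate * (1 - sim$rejection_rate) / 4000))
})

test_that("null simulations are calibrated near alpha for the Welch test", {
  null_cfg <- planning_config(0, 0, 1, 4, 1, 1)
  sim <- simulate_type1(null_cfg, 20, 20, reps = 4000, seed = 5)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(sim$rejection_rate - 0.05), 3 * se + 0.005)
  expect_error(simulate_type1(table6_case11, 10, 10), "equal slopes")
})

test_that("the pooled test loses size control under inverse pairing", {
  # larger error variance in the smaller group inflates the pooled size
  inv <- planning_config(0, 0, 4, 1, 1, 1)
  pooled <- simulate_type1(inv, 11, 33, reps = 6000, seed = 12,
                           test = "pooled")
  welch <- simulate_type1(inv, 11, 33, reps = 6000, seed = 12)
  se <- sqrt(0.05 * 0.95 / 6000)
  expect_gt(abs(pooled$rejection_rate - 0.05), 3 * se)
  expect_lt(abs(welch$rejection_rate - 0.05), 3 * se + 0.005)
})

test_that("empirical rates disperse like a binomial across seeds", {
  cfg <- planning_config(0.8, 0, 1, 1, 1, 1)
  reps <- 400L
  rates <- sapply(1:20, function(s)
    simulate_rejection_rate(cfg, 10, 10, reps = reps,
                            seed = 1000 + s)$rejection_rate)
  p <- mean(rates)
  # chi-square dispersion statistic for 20 binomial proportions
  disp <- sum((rates - p)^2) * reps / (p * (1 - p))
  expect_gt(disp, qchisq(0.0005, df = 19))
  expect_lt(disp, qchisq(0.9995, df = 19))
})

test_that("the variance-pattern grid enumerates the 15 benchmark cases", {
  vc <- variance_cases()
  expect_identical(nrow(vc), 15L)
  expect_identical(vc$case, 1:15)
  # cases 11-15 are the inverse-pairing predictor block tau = (4, 1)
  expect_true(all(vc$tau2_1[11:15] == 4 & vc$tau2_2[11:15] == 1))
  expect_identical(c(vc$sigma2_1[11], vc$sigma2_2[11]), c(1, 1))
})

test_that("table regeneration reproduces planned sizes and powers", {
  row <- reproduce_table(beta1d = 1, ratio = 3, reps = 500, seed = 3,
                         cases = 11)
  expect_identical(c(row$st_n1, row$st_n2), c(6L, 18L))
  expect_identical(c(row$mt_n1, row$mt_n2, row$mt_nt), c(8L, 24L, 32L))
  expect_4dp(row$delta_star, 0.1263)
  expect_4dp(row$st_estimated, 0.8050)
  expect_equal(row$mt_estimated, 0.8578, tolerance = 5e-4)
  # mixed-t analytic power tracks its own simulation at smoke scale
  expect_lt(abs(row$mt_error), 3 * sqrt(0.86 * 0.14 / 500) + 0.005)

  row1 <- reproduce_table(beta1d = 0.5, ratio = 1, reps = 500, seed = 3,
                          cases = 1)
  expect_identical(c(row1$st_n1, row1$st_n2), c(65L, 65L))
  expect_identical(c(row1$mt_n1, row1$mt_n2), c(67L, 67L))
  expect_4dp(row1$st_estimated, 0.8015)
  expect_equal(row1$mt_estimated, 0.8025, tolerance = 5e-4)
})

test_that("regenerated planning columns match the large-effect benchmark table", {
  # analytic halves (sizes, delta*, estimated powers) of the full
  # slope-difference-1, ratio-3 table; simulation columns excluded
  expected <- data.frame(
    case = 1:15,
    delta = c(0.0581, 0.0487, 0.0360, 0.0349, 0.0195, 0.0665, 0.0642,
              0.0581, 0.0378, 0.0206, 0.1263, 0.0845, 0.0523, 0.0874,
              0.0581),
    st_n1 = c(13L, 15L, 20L, 21L, 37L, 12L, 12L, 13L, 20L, 35L, 6L, 9L,
              14L, 9L, 13L),
    st_est = c(0.8160, 0.8088, 0.8097, 0.8057, 0.8040, 0.8317, 0.8145,
               0.8160, 0.8186, 0.8009, 0.8050, 0.8378, 0.8187, 0.8413,
               0.8160),
    mt_n1 = c(14L, 17L, 21L, 23L, 39L, 13L, 13L, 14L, 21L, 37L, 8L, 10L,
              15L, 10L, 14L),
    mt_est = c(0.8035, 0.8261, 0.8061, 0.8157, 0.8088, 0.8158, 0.8011,
               0.8035, 0.8075, 0.8059, 0.8578, 0.8347, 0.8232, 0.8246,
               0.8035))
  for (i in 1:15) {
    cc <- variance_cases()[i, ]
    cfg <- planning_config(1, 0, cc$sigma2_1, cc$sigma2_2,
                           cc$tau2_1, cc$tau2_2)
    st <- sample_size_slopes(cfg, ratio = 3, method = "ST")
    mt <- sample_size_slopes(cfg, ratio = 3, method = "MT")
    expect_identical(st$n1, expected$st_n1[i])
    expect_identical(st$n2, 3L * expected$st_n1[i])
    expect_identical(mt$n1, expected$mt_n1[i])
    expect_4dp(st$achieved_power, expected$st_est[i])
    expect_equal(mt$achieved_power, expected$mt_est[i], tolerance = 5e-4)
    expect_4dp(effect_size_delta_star(cfg, st$n1, st$n2),
               expected$delta[i])
    # the simplified method never plans larger studies than the mixed
    expect_lte(st$n1, mt$n1)
  }
})
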