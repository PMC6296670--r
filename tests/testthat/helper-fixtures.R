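# shared fixtures and independent oracles

mice <- bishop_mice()

# a random raw two-group data set with heterogeneous variances
random_groups <- function(seed, n1 = 12L, n2 = 20L) {
  set.seed(seed)
  x1 <- rnorm(n1, 40, 6); y1 <- 3 + 1.2 * x1 + rnorm(n1, sd = 5)
  x2 <- rnorm(n2, 34, 5); y2 <- 1 + 0.4 * x2 + rnorm(n2, sd = 2)
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# a random pair of group summaries (for property tests on the statistic)
random_summaries <- function(seed) {
  set.seed(seed)
  make <- function() group_summary(
    n = sample(4:40, 1L),
    slope = rnorm(1L),
    ssx = rchisq(1L, 10) + 0.5,
    sigma2 = rchisq(1L, 5) + 0.1)
  list(s1 = make(), s2 = make())
}

# least-squares slope/intercept straight from the normal equations,
# independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  list(slope = slope, intercept = intercept,
       sse = sum((y - fitted)^2),
       ssx = sum(x^2) - sum(x)^2 / n)
}

# two-sided t-tail probability by adaptive quadrature of the density,
# not via pt()
t_pvalue_oracle <- function(tstat, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# agreement with a value printed to 4 decimal places
expect_4dp <- function(actual, printed) {
  expect_equal(round(actual, 4L), printed)
}

table6_case11 <- planning_config(beta11 = 1, beta12 = 0,
                                 sigma2_1 = 1, sigma2_2 = 1,
                                 tau2_1 = 4, tau2_2 = 1)
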