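#' Monte Carlo rejection rate of a slope-comparison test
#'
#' Simulates the two-group random-predictor regression model and
#' estimates the rejection rate of the extended Welch test (or the
#' classical pooled-variance test).  Per replicate, each group's
#' predictors are drawn \eqn{N(\theta_i, \tau_i^2)}, responses follow
#' \eqn{y = \beta_{0i} + \beta_{1i} x + N(0, \sigma_i^2)} noise, and the
#' selected two-sided test is run at `config$alpha`.  Under the
#' alternative the rate estimates true unconditional power; under
#' \eqn{\beta_{11} = \beta_{12}} it estimates the type I error.
#'
#' All per-group regression quantities are computed in closed form
#' across replicates, so 10,000 replicates run in well under a second at
#' table-scale sizes.  Replicates whose predictor sum of squares
#' underflows to zero (essentially impossible for continuous normals;
#' guarded against numerical pathologies) are redrawn and counted.
#'
#' @param config a [planning_config()]; intercepts and predictor means
#'   are taken from it (defaults 0).
#' @param n1,n2 group sizes (integers, at least 3).
#' @param reps number of replicates (at least 100; default 10000).
#' @param seed integer seed; identical `(config, sizes, reps, seed)`
#'   give bit-identical results.
#' @param test `"welch"` (default) or `"pooled"`.
#'
#' @return An object of class `"slope_sim"`: a list with
#'   `rejection_rate`, `mc_se` (binomial standard error), `reps`,
#'   `test`, `redraws` (degenerate replicates redrawn), and -- for the
#'   Welch test with planning-admissible sizes -- the matching analytic
#'   powers `analytic_st`, `analytic_mt` and their errors
#'   `error_st`, `error_mt` (analytic minus empirical).
#'
#' @examples
#' cfg <- planning_config(1, 0, 1, 1, 4, 1)
#' simulate_rejection_rate(cfg, 6, 18, reps = 2000, seed = 1)
#' @export
simulate_rejection_rate <- function(config, n1, n2, reps = 10000L,
                                    seed = NULL,
                                    test = c("welch", "pooled")) {
  assert_planning_config(config)
  test <- match.arg(test)
  for (nm in c("n1", "n2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v != round(v) || v < 3)
      stop("'", nm, "' must be an integer >= 3", call. = FALSE)
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  reps <- as.integer(reps)
  if (reps < 100L) stop("'reps' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  g1 <- sim_group_stats(reps, n1, config$theta1, config$tau2_1,
                        config$beta01, config$beta11, config$sigma2_1)
  g2 <- sim_group_stats(reps, n2, config$theta2, config$tau2_2,
                        config$beta02, config$beta12, config$sigma2_2)

  if (test == "welch") {
    a1 <- g1$sigma2 / g1$ssx
    a2 <- g2$sigma2 / g2$ssx
    tstat <- (g1$slope - g2$slope) / sqrt(a1 + a2)
    s <- a1 + a2
    nu <- 1 / ((a1 / s)^2 / (n1 - 2L) + (a2 / s)^2 / (n2 - 2L))
  } else {
    sp2 <- (g1$sse + g2$sse) / (n1 + n2 - 4L)
    tstat <- (g1$slope - g2$slope) /
      sqrt(sp2 * (1 / g1$ssx + 1 / g2$ssx))
    nu <- rep.int(n1 + n2 - 4L, reps)
  }
  reject <- abs(tstat) > stats::qt(1 - config$alpha / 2, nu)
  rate <- mean(reject)

  out <- list(rejection_rate = rate,
              mc_se = sqrt(rate * (1 - rate) / reps),
              reps = reps, test = test, n1 = n1, n2 = n2,
              alpha = config$alpha,
              redraws = g1$redraws + g2$redraws,
              analytic_st = NA_real_, analytic_mt = NA_real_,
              error_st = NA_real_, error_mt = NA_real_)
  if (test == "welch" && n1 >= 4L && n2 >= 4L) {
    out$analytic_st <- power_simplified(config, n1, n2)$power
    out$analytic_mt <- power_mixed(config, n1, n2)$power
    out$error_st <- out$analytic_st - rate
    out$error_mt <- out$analytic_mt - rate
  }
  structure(out, class = "slope_sim")
}

# closed-form per-group regression statistics for all replicates at once:
# columns of an n x reps matrix are independent data sets
sim_group_stats <- function(reps, n, theta, tau2, beta0, beta1, sigma2) {
  x <- matrix(stats::rnorm(n * reps, theta, sqrt(tau2)), n, reps)
  y <- beta0 + beta1 * x +
    matrix(stats::rnorm(n * reps, 0, sqrt(sigma2)), n, reps)
  xbar <- colMeans(x); ybar <- colMeans(y)
  ssx <- colSums(x * x) - n * xbar^2
  redraws <- 0L
  bad <- which(ssx <= 0)
  while (length(bad)) {
    redraws <- redraws + length(bad)
    x[, bad] <- stats::rnorm(n * length(bad), theta, sqrt(tau2))
    y[, bad] <- beta0 + beta1 * x[, bad] +
      stats::rnorm(n * length(bad), 0, sqrt(sigma2))
    xbar <- colMeans(x); ybar <- colMeans(y)
    ssx <- colSums(x * x) - n * xbar^2
    bad <- which(ssx <= 0)
  }
  sxy <- colSums(x * y) - n * xbar * ybar
  ssy <- colSums(y * y) - n * ybar^2
  slope <- sxy / ssx
  sse <- pmax(ssy - slope * sxy, 0)
  list(slope = slope, ssx = ssx, sse = sse, sigma2 = sse / (n - 2L),
       redraws = redraws)
}

#' @export
print.slope_sim <- function(x, digits = 4L, ...) {
  cat(sprintf("Monte Carlo rejection rate (%s test, %d replicates)\n",
              x$test, x$reps))
  cat(sprintf("  n1 = %d, n2 = %d, alpha = %g\n", x$n1, x$n2, x$alpha))
  cat(sprintf("  empirical rate = %.*f (MC SE %.*f)\n",
              digits, x$rejection_rate, digits, x$mc_se))
  if (!is.na(x$analytic_mt))
    cat(sprintf(
      "  analytic ST = %.*f (error %+.*f); analytic MT = %.*f (error %+.*f)\n",
      digits, x$analytic_st, digits, x$error_st,
      digits, x$analytic_mt, digits, x$error_mt))
  if (x$redraws > 0)
    cat(sprintf("  degenerate replicates redrawn: %d\n", x$redraws))
  invisible(x)
}

#' Simulated type I error of a slope-comparison test
#'
#' Convenience wrapper around [simulate_rejection_rate()] that enforces
#' the null \eqn{\beta_{11} = \beta_{12}}: supplying a configuration
#' with unequal slopes is an error.  The rejection rate then estimates
#' the actual size of the nominal-`alpha` test.
#'
#' @inheritParams simulate_rejection_rate
#' @return As [simulate_rejection_rate()].
#' @examples
#' cfg <- planning_config(0, 0, 4, 1, 1, 1)
#' simulate_type1(cfg, 10, 30, reps = 2000, seed = 1)
#' @export
simulate_type1 <- function(config, n1, n2, reps = 10000L, seed = NULL,
                           test = c("welch", "pooled")) {
  assert_planning_config(config)
  if (config$beta1d != 0)
    stop("type-I-error simulation requires equal slopes ",
         "(beta11 = beta12); got a slope difference of ", config$beta1d,
         call. = FALSE)
  simulate_rejection_rate(config, n1, n2, reps = reps, seed = seed,
                          test = test)
}

#' The 15 variance patterns of the planning study grid
#'
#' The benchmark grid crosses three predictor-variance patterns
#' \eqn{\{\tau_1^2, \tau_2^2\} \in \{(1,1), (1,4), (4,1)\}} with five
#' error-variance patterns \eqn{\{\sigma_1^2, \sigma_2^2\} \in
#' \{(1,1), (1,2), (1,4), (2,1), (4,1)\}}, covering balanced,
#' direct-paired and inverse-paired heteroscedasticity.
#'
#' @return A 15-row data frame with columns `case`, `tau2_1`, `tau2_2`,
#'   `sigma2_1`, `sigma2_2`.
#' @export
variance_cases <- function() {
  tau <- rbind(c(1, 1), c(1, 4), c(4, 1))
  sig <- rbind(c(1, 1), c(1, 2), c(1, 4), c(2, 1), c(4, 1))
  g <- expand.grid(s = seq_len(nrow(sig)), t = seq_len(nrow(tau)))
  data.frame(case = seq_len(nrow(g)),
             tau2_1 = tau[g$t, 1L], tau2_2 = tau[g$t, 2L],
             sigma2_1 = sig[g$s, 1L], sigma2_2 = sig[g$s, 2L])
}

#' Regenerate one benchmark table of sizes, powers and simulation errors
#'
#' For a given slope difference and allocation ratio, runs the full
#' planning pipeline over the 15 variance patterns of
#' [variance_cases()]: solve the minimal sample size at nominal power
#' 0.80 for each method, evaluate its analytic power, simulate the
#' empirical power at the planned sizes, and report the analytic-minus-
#' empirical error.
#'
#' @param beta1d slope difference (group-2 slope fixed at 0).
#' @param ratio allocation ratio `n2/n1`.
#' @param reps Monte Carlo replicates per cell (default 10000; reduce
#'   for smoke runs).
#' @param seed integer seed; each cell uses a seed derived
#'   deterministically from it, so tables are reproducible cell by cell.
#' @param target_power nominal power (default 0.80).
#' @param alpha significance level (default 0.05).
#' @param cases subset of case numbers 1..15 (default all).
#' @param progress emit one line per case to standard error.
#'
#' @return A data frame with one row per case: the variance patterns,
#'   `delta_star` (at the simplified-method sizes), and for each method
#'   the planned `n1`, `n2`, `n_t`, `estimated` (analytic) power,
#'   `simulated` power, and `error`.
#' @examples
#' reproduce_table(beta1d = 1, ratio = 3, reps = 500, seed = 1,
#'                 cases = 11)
#' @export
reproduce_table <- function(beta1d, ratio, reps = 10000L, seed = 1L,
                            target_power = 0.80, alpha = 0.05,
                            cases = 1:15, progress = FALSE) {
  vc <- variance_cases()
  if (!all(cases %in% vc$case)) stop("'cases' must be within 1..15",
                                     call. = FALSE)
  rows <- lapply(cases, function(i) {
    cc <- vc[vc$case == i, ]
    cfg <- planning_config(beta11 = beta1d, beta12 = 0,
                           sigma2_1 = cc$sigma2_1, sigma2_2 = cc$sigma2_2,
                           tau2_1 = cc$tau2_1, tau2_2 = cc$tau2_2,
                           alpha = alpha)
    out <- data.frame(case = i, tau2_1 = cc$tau2_1, tau2_2 = cc$tau2_2,
                      sigma2_1 = cc$sigma2_1, sigma2_2 = cc$sigma2_2)
    for (method in c("ST", "MT")) {
      ss <- sample_size_slopes(cfg, target_power = target_power,
                               ratio = ratio, method = method)
      # distinct deterministic substream per (case, method) cell
      cell_seed <- (as.integer(seed) + 7919L * i +
                      1000003L * (method == "MT")) %% .Machine$integer.max
      sim <- simulate_rejection_rate(cfg, ss$n1, ss$n2, reps = reps,
                                     seed = cell_seed)
      pre <- tolower(method)
      out[[paste0(pre, "_n1")]] <- ss$n1
      out[[paste0(pre, "_n2")]] <- ss$n2
      out[[paste0(pre, "_nt")]] <- ss$n_t
      out[[paste0(pre, "_estimated")]] <- ss$achieved_power
      out[[paste0(pre, "_simulated")]] <- sim$rejection_rate
      out[[paste0(pre, "_error")]] <- ss$achieved_power - sim$rejection_rate
      if (method == "ST")
        out$delta_star <- effect_size_delta_star(cfg, ss$n1, ss$n2)
    }
    if (progress)
      message(sprintf("case %2d done (ST n=%d+%d, MT n=%d+%d)", i,
                      out$st_n1, out$st_n2, out$mt_n1, out$mt_n2))
    out
  })
  res <- do.call(rbind, rows)
  cols <- c("case", "tau2_1", "tau2_2", "sigma2_1", "sigma2_2",
            "delta_star",
            "st_n1", "st_n2", "st_nt", "st_estimated", "st_simulated",
            "st_error",
            "mt_n1", "mt_n2", "mt_nt", "mt_estimated", "mt_simulated",
            "mt_error")
  res[, cols]
}
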