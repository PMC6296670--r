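#' Population configuration for power and sample-size planning
#'
#' Collects the population quantities that drive the unconditional power
#' of the extended Welch slope test: the two slopes, the two error
#' variances \eqn{\sigma_1^2, \sigma_2^2}, the two predictor variances
#' \eqn{\tau_1^2, \tau_2^2}, and the significance level.  Intercepts and
#' predictor means may be recorded for completeness but do not enter any
#' power formula: slope inference is invariant to location shifts of
#' either variable.
#'
#' @param beta11,beta12 population slopes of groups 1 and 2 (response
#'   units per predictor unit).
#' @param sigma2_1,sigma2_2 error variances, strictly positive.
#' @param tau2_1,tau2_2 predictor variances, strictly positive.  At the
#'   design stage the predictors are treated as random
#'   \eqn{N(\theta_i, \tau_i^2)} draws, so the observed predictor sum of
#'   squares \eqn{SSX_i} is \eqn{\tau_i^2} times a chi-square variate
#'   with \eqn{n_i - 1} degrees of freedom.
#' @param theta1,theta2 predictor means (default 0; power-irrelevant).
#' @param beta01,beta02 intercepts (default 0; power-irrelevant).
#' @param alpha significance level of the planned two-sided test.
#'
#' @return An object of class `"planning_config"`; a list of the above
#'   with the derived slope difference `beta1d = beta11 - beta12`.
#'
#' @examples
#' planning_config(beta11 = 0.5, beta12 = 0,
#'                 sigma2_1 = 1, sigma2_2 = 1,
#'                 tau2_1 = 1, tau2_2 = 1)
#' @export
planning_config <- function(beta11, beta12,
                            sigma2_1, sigma2_2,
                            tau2_1, tau2_2,
                            theta1 = 0, theta2 = 0,
                            beta01 = 0, beta02 = 0,
                            alpha = 0.05) {
  check_alpha(alpha)
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(v)
  }
  for (nm in c("beta11", "beta12", "theta1", "theta2", "beta01", "beta02"))
    assign(nm, num1(get(nm), nm))
  for (nm in c("sigma2_1", "sigma2_2", "tau2_1", "tau2_2")) {
    v <- num1(get(nm), nm)
    if (v <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
    assign(nm, v)
  }
  structure(
    list(beta11 = beta11, beta12 = beta12, beta1d = beta11 - beta12,
         sigma2_1 = sigma2_1, sigma2_2 = sigma2_2,
         tau2_1 = tau2_1, tau2_2 = tau2_2,
         theta1 = theta1, theta2 = theta2,
         beta01 = beta01, beta02 = beta02,
         alpha = alpha),
    class = "planning_config")
}

#' @export
print.planning_config <- function(x, ...) {
  cat("Planning configuration for the extended Welch slope test\n")
  cat(sprintf("  slopes: beta11 = %g, beta12 = %g (difference %g)\n",
              x$beta11, x$beta12, x$beta1d))
  cat(sprintf("  error variances: %g, %g\n", x$sigma2_1, x$sigma2_2))
  cat(sprintf("  predictor variances: %g, %g\n", x$tau2_1, x$tau2_2))
  cat(sprintf("  alpha = %g\n", x$alpha))
  invisible(x)
}

assert_planning_config <- function(config) {
  if (!inherits(config, "planning_config"))
    stop("'config' must be a 'planning_config' object", call. = FALSE)
  invisible(config)
}

# planning designs need c_i >= 2 and at least 3 df in each chi-square
# mixing distribution
check_sizes <- function(n1, n2, floor = 4L) {
  for (nm in c("n1", "n2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v != round(v) || v < floor)
      stop("'", nm, "' must be an integer >= ", floor, call. = FALSE)
  }
  c(as.integer(n1), as.integer(n2))
}

#' Expected noncentrality of the extended Welch statistic
#'
#' The noncentrality parameter of the planned test with each random
#' predictor sum of squares replaced by its expectation
#' \eqn{E(SSX_i) = (n_i - 1)\tau_i^2}:
#' \deqn{\Delta^* = \frac{\beta_{1D}}
#'   {\{\sigma_1^2/((n_1-1)\tau_1^2) +
#'      \sigma_2^2/((n_2-1)\tau_2^2)\}^{1/2}}.}
#'
#' @param config a [planning_config()].
#' @param n1,n2 planned group sizes (integers, at least 4).
#' @return The noncentrality \eqn{\Delta^*} (signed).
#' @seealso [effect_size_delta_star()], [power_simplified()]
#' @export
expected_ncp <- function(config, n1, n2) {
  assert_planning_config(config)
  n <- check_sizes(n1, n2)
  a1 <- config$sigma2_1 / ((n[1L] - 1) * config$tau2_1)
  a2 <- config$sigma2_2 / ((n[2L] - 1) * config$tau2_2)
  config$beta1d / sqrt(a1 + a2)
}

#' Working (standardized) effect size
#'
#' The dimensionless effect summary \eqn{\delta^* = \Delta^*/N_T} where
#' \eqn{\Delta^*} is [expected_ncp()] and \eqn{N_T = n_1 + n_2}.  It
#' folds the slope difference, both error variances, both predictor
#' variances and the allocation into a single per-subject standardized
#' difference, and is the quantity tabulated alongside planned sample
#' sizes.
#'
#' @inheritParams expected_ncp
#' @return \eqn{\delta^*} (signed).
#' @export
effect_size_delta_star <- function(config, n1, n2) {
  expected_ncp(config, n1, n2) / (n1 + n2)
}

#' Plug-in approximate degrees of freedom for planning
#'
#' The Satterthwaite-type degrees-of-freedom formula of [welch_df()]
#' evaluated at the population variances and the expected predictor sums
#' of squares \eqn{(n_i - 1)\tau_i^2}; used by the simplified-t power
#' approximation.
#'
#' @inheritParams expected_ncp
#' @return The plug-in degrees of freedom \eqn{\nu^*}.
#' @export
plugin_df <- function(config, n1, n2) {
  assert_planning_config(config)
  n <- check_sizes(n1, n2)
  a1 <- config$sigma2_1 / ((n[1L] - 1) * config$tau2_1)
  a2 <- config$sigma2_2 / ((n[2L] - 1) * config$tau2_2)
  w1 <- a1 / (a1 + a2)
  w2 <- a2 / (a1 + a2)
  1 / (w1^2 / (n[1L] - 2L) + w2^2 / (n[2L] - 2L))
}
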