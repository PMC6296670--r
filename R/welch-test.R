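#' Extended Welch statistic for a difference of two regression slopes
#'
#' Computes the slope difference, its heteroscedasticity-respecting
#' standard error and the extended Welch statistic
#' \deqn{T^* = \frac{\hat\beta_{11} - \hat\beta_{12}}
#'   {(\hat\sigma_1^2/SSX_1 + \hat\sigma_2^2/SSX_2)^{1/2}},}
#' in which each group contributes its own error-variance estimate.  This
#' is the slope analogue of Welch's unequal-variance two-sample statistic
#' for the Behrens-Fisher problem.
#'
#' @param s1,s2 [group_summary()] objects for the two groups.
#'
#' @return A list with components `slope_diff`, `se` and `t_star`.
#'
#' @seealso [welch_slope_test()] for the full test, [welch_df()] for the
#'   approximate degrees of freedom.
#' @export
welch_statistic <- function(s1, s2) {
  assert_group_summary(s1, "s1"); assert_group_summary(s2, "s2")
  v <- s1$sigma2 / s1$ssx + s2$sigma2 / s2$ssx
  if (v <= 0)
    stop("zero standard error: both variance components vanish",
         call. = FALSE)
  d <- s1$slope - s2$slope
  list(slope_diff = d, se = sqrt(v), t_star = d / sqrt(v))
}

#' Satterthwaite-type approximate degrees of freedom
#'
#' The approximate degrees of freedom of the extended Welch statistic,
#' obtained by moment matching of the weighted sum of scaled chi-square
#' variance estimates:
#' \deqn{1/\hat\nu = w_1^2/c_1 + w_2^2/c_2, \quad
#'   w_i = \frac{\hat\sigma_i^2/SSX_i}
#'              {\hat\sigma_1^2/SSX_1 + \hat\sigma_2^2/SSX_2},}
#' with \eqn{c_i = n_i - 2} the residual degrees of freedom.  Always lies
#' between \eqn{\min(c_1, c_2)} and \eqn{c_1 + c_2}.
#'
#' @inheritParams welch_statistic
#' @return The approximate degrees of freedom (a positive real).
#' @export
welch_df <- function(s1, s2) {
  assert_group_summary(s1, "s1"); assert_group_summary(s2, "s2")
  a1 <- s1$sigma2 / s1$ssx
  a2 <- s2$sigma2 / s2$ssx
  if (a1 + a2 <= 0)
    stop("degenerate variance components: a1 + a2 = 0", call. = FALSE)
  w1 <- a1 / (a1 + a2)
  w2 <- a2 / (a1 + a2)
  1 / (w1^2 / s1$c + w2^2 / s2$c)
}

welch_result <- function(s1, s2, stat, df, alpha, method) {
  crit <- stats::qt(1 - alpha / 2, df)
  p <- 2 * stats::pt(abs(stat$t_star), df, lower.tail = FALSE)
  structure(
    list(statistic = c("t" = stat$t_star),
         parameter = c("df" = df),
         p.value = p,
         estimate = c("slope difference" = stat$slope_diff),
         stderr = stat$se,
         alternative = "two.sided",
         method = method,
         data.name = sprintf("group 1 (n = %d) vs group 2 (n = %d)",
                             s1$n, s2$n),
         alpha = alpha,
         crit = crit,
         # strict inequality: the boundary |t*| = critical value does not
         # reject
         reject = abs(stat$t_star) > crit),
    class = c("welch_slope_test", "htest"))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L ||
      !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number strictly between 0 and 1",
         call. = FALSE)
  alpha
}

#' Extended Welch test of parallelism of two regression lines
#'
#' Tests \eqn{H_0: \beta_{11} = \beta_{12}} against the two-sided
#' alternative without assuming equal error variances.  The statistic of
#' [welch_statistic()] is referred to a central t distribution with the
#' approximate degrees of freedom of [welch_df()]; the null is rejected
#' when \eqn{|T^*|} strictly exceeds the upper \eqn{\alpha/2} t quantile.
#'
#' Equality of slopes is equivalent to the absence of a treatment by
#' covariate interaction in the combined dichotomous-moderator
#' regression, so this is the heteroscedasticity-robust interaction test
#' for two groups.
#'
#' @inheritParams welch_statistic
#' @param alpha significance level (default 0.05).
#'
#' @return An object of classes `"welch_slope_test"` and `"htest"` with
#'   the usual components (`statistic`, `parameter`, `p.value`,
#'   `estimate`, `stderr`) plus `alpha`, `crit` (the critical value) and
#'   `reject`.
#'
#' @examples
#' ## diabetic vs normal mice: kidney weight regressed on body weight,
#' ## entered through the published per-group summary statistics
#' m <- bishop_mice()
#' welch_slope_test(m$group1, m$group2)
#'
#' @references
#' Welch, B. L. (1938). The significance of the difference between two
#' means when the population variances are unequal. Biometrika 29,
#' 350-362.
#' @export
welch_slope_test <- function(s1, s2, alpha = 0.05) {
  check_alpha(alpha)
  stat <- welch_statistic(s1, s2)
  df <- welch_df(s1, s2)
  welch_result(s1, s2, stat, df, alpha,
               "Extended Welch test of equality of two regression slopes")
}

#' Classical pooled-variance test of equality of two slopes
#'
#' The textbook comparison test that assumes a common error variance:
#' residual sums of squares are pooled into
#' \eqn{S_p^2 = (SSE_1 + SSE_2)/(n_1 + n_2 - 4)} and the slope difference
#' is referred to a t distribution with \eqn{n_1 + n_2 - 4} degrees of
#' freedom.  Included as the benchmark whose type-I-error control breaks
#' down under variance heterogeneity, especially with unequal group
#' sizes.
#'
#' @inheritParams welch_slope_test
#' @return As [welch_slope_test()].
#' @examples
#' m <- bishop_mice()
#' pooled_slope_test(m$group1, m$group2)
#' @export
pooled_slope_test <- function(s1, s2, alpha = 0.05) {
  check_alpha(alpha)
  assert_group_summary(s1, "s1"); assert_group_summary(s2, "s2")
  df <- s1$n + s2$n - 4L
  if (df < 1L) stop("need n1 + n2 > 4 for the pooled test", call. = FALSE)
  sp2 <- (s1$sse + s2$sse) / df
  v <- sp2 * (1 / s1$ssx + 1 / s2$ssx)
  if (v <= 0) stop("zero standard error in pooled test", call. = FALSE)
  d <- s1$slope - s2$slope
  stat <- list(slope_diff = d, se = sqrt(v), t_star = d / sqrt(v))
  welch_result(s1, s2, stat, df, alpha,
               "Pooled-variance test of equality of two regression slopes")
}

#' @export
print.welch_slope_test <- function(x, digits = 4L, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("data: ", x$data.name, "\n", sep = "")
  cat(sprintf("t* = %.*f, df = %.*f, p-value = %.*f\n",
              digits, unname(x$statistic), digits, unname(x$parameter),
              digits, x$p.value))
  cat(sprintf("slope difference = %.*f (SE = %.*f)\n",
              digits, unname(x$estimate), digits, x$stderr))
  cat(sprintf("alpha = %g, critical value = %.*f: %s H0 of equal slopes\n",
              x$alpha, digits, x$crit,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}
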