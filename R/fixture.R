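#' Published summary statistics of the diabetic-mice organ-weight study
#'
#' Per-group simple-regression summaries for the classic example of
#' kidney weight (response, in grams scaled) regressed on body weight
#' (grams) in crossbred diabetic mice (group 1, n = 9) and normal mice
#' (group 2, n = 25), from Bishop's organ-weight data.  Only the
#' published summary statistics are available, not the raw
#' measurements, so the groups are represented as [group_summary()]
#' objects built from those numbers:
#'
#' * slopes 15.9286 and 3.8398,
#' * error-variance estimates 10124.8980 and 9097.9625,
#' * predictor (body-weight) variances 31.1111 and 23.8600, from which
#'   each SSX is reconstructed as \eqn{(n - 1)\hat\tau^2},
#' * body-weight means 42.8889 and 33.8800.
#'
#' The question of interest is whether kidney weight grows
#' disproportionately with body weight in the diabetic mice, i.e.
#' whether the two slopes differ.
#'
#' @return A list with components `group1` and `group2`
#'   ([group_summary()] objects) and `planning` (a [planning_config()]
#'   that treats the estimates as planning values for future studies,
#'   at `alpha = 0.05`).
#'
#' @examples
#' m <- bishop_mice()
#' welch_slope_test(m$group1, m$group2)
#' power_mixed(m$planning, 9, 25)
#'
#' @references
#' Bishop's organ- and body-weight measurements for crossbred diabetic
#' and normal mice; only the published per-group summary statistics are
#' reproduced here.
#' @export
bishop_mice <- function() {
  g1 <- group_summary(n = 9, slope = 15.9286, tau2 = 31.1111,
                      sigma2 = 10124.8980, xbar = 42.8889,
                      label = "diabetic")
  g2 <- group_summary(n = 25, slope = 3.8398, tau2 = 23.8600,
                      sigma2 = 9097.9625, xbar = 33.8800,
                      label = "normal")
  list(group1 = g1, group2 = g2,
       planning = planning_config(beta11 = 15.9286, beta12 = 3.8398,
                                  sigma2_1 = 10124.8980,
                                  sigma2_2 = 9097.9625,
                                  tau2_1 = 31.1111, tau2_2 = 23.8600,
                                  theta1 = 42.8889, theta2 = 33.8800,
                                  alpha = 0.05))
}
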