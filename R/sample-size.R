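#' Minimal sample sizes attaining a nominal power
#'
#' Finds the smallest group sizes, at a fixed allocation ratio
#' `r = n2/n1`, whose planned design attains the nominal power of the
#' two-sided extended Welch slope test, using either the mixed-t
#' (recommended) or simplified-t power function.  `n2` is tied to `n1`
#' by `n2 = ceiling(ratio * n1)`; `n1` is the smallest integer at or
#' above `n1_floor` whose scheme reaches `target_power`.
#'
#' The search seeds `n1` from a normal-approximation solution of
#' \eqn{\Delta^* = z_{\alpha/2} + z_{\beta}}, then steps down to the
#' last failing size and up to the first attaining one, so the returned
#' scheme is minimal whenever power is monotone in `n1` (which it is for
#' these power functions); minimality is also verified directly.
#'
#' @param config a [planning_config()]; must have a nonzero slope
#'   difference.
#' @param target_power nominal power, strictly between `config$alpha`
#'   and 1 (default 0.80).
#' @param ratio allocation ratio `n2/n1` (default 1).
#' @param method `"MT"` (mixed-t, default) or `"ST"` (simplified-t).
#' @param n1_floor smallest admissible `n1` (default 4).
#' @param n1_cap search ceiling (default 1e5).
#'
#' @return An object of class `"slope_samplesize"`: a list with `n1`,
#'   `n2`, `n_t`, `achieved_power`, `method`, `target_power`, `ratio`
#'   and `trace` (a data frame of the `(n1, power)` evaluations made).
#'
#' @examples
#' m <- bishop_mice()
#' sample_size_slopes(m$planning, target_power = 0.80, ratio = 1)
#' @export
sample_size_slopes <- function(config, target_power = 0.80, ratio = 1,
                               method = c("MT", "ST"),
                               n1_floor = 4L, n1_cap = 1e5L) {
  assert_planning_config(config)
  method <- match.arg(method)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("'ratio' must be a single positive number", call. = FALSE)
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= config$alpha || target_power >= 1)
    stop("'target_power' must lie strictly between alpha (",
         config$alpha, ") and 1: power above the type-I rate is ",
         "unattainable otherwise", call. = FALSE)
  if (config$beta1d == 0)
    stop("slope difference is 0: power never exceeds alpha, no finite ",
         "sample size attains ", target_power, call. = FALSE)
  n1_floor <- max(4L, as.integer(n1_floor))

  n2_of <- function(n1) max(as.integer(ceiling(ratio * n1)), 4L)
  cache <- new.env(parent = emptyenv())
  evals <- list()
  pw <- function(n1) {
    key <- as.character(n1)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (method == "MT")
      power_mixed(config, n1, n2_of(n1))$power
    else
      power_simplified(config, n1, n2_of(n1))$power
    cache[[key]] <- p
    evals[[length(evals) + 1L]] <<- data.frame(n1 = n1, power = p)
    p
  }

  # normal-approximation seed: Delta* = z_{alpha/2} + z_{beta}
  zq <- stats::qnorm(1 - config$alpha / 2) + stats::qnorm(target_power)
  a0 <- config$sigma2_1 / config$tau2_1
  b0 <- config$sigma2_2 / (ratio * config$tau2_2)
  n_seed <- (zq / config$beta1d)^2 * (a0 + b0) + 1
  n1 <- max(n1_floor, min(as.integer(ceiling(n_seed)), as.integer(n1_cap)))

  if (pw(n1) >= target_power) {
    while (n1 > n1_floor && pw(n1 - 1L) >= target_power) n1 <- n1 - 1L
  } else {
    repeat {
      n1 <- n1 + 1L
      if (n1 > n1_cap)
        stop("sample-size search exceeded the ceiling n1_cap = ", n1_cap,
             call. = FALSE)
      if (pw(n1) >= target_power) break
    }
  }

  trace <- do.call(rbind, evals)
  trace <- trace[order(trace$n1), , drop = FALSE]
  rownames(trace) <- NULL
  # the search objective must be non-decreasing along the visited sizes
  if (is.unsorted(trace$power))
    stop("internal error: power not monotone in n1 along the search ",
         "trace", call. = FALSE)
  n2 <- n2_of(n1)
  structure(
    list(n1 = n1, n2 = n2, n_t = n1 + n2,
         achieved_power = pw(n1),
         method = method, target_power = target_power, ratio = ratio,
         trace = trace),
    class = "slope_samplesize")
}

#' @export
print.slope_samplesize <- function(x, digits = 4L, ...) {
  lab <- switch(x$method, ST = "simplified-t", MT = "mixed-t", x$method)
  cat("Minimal sample sizes for the extended Welch slope test\n")
  cat(sprintf("  method = %s, nominal power = %g, ratio n2/n1 = %g\n",
              lab, x$target_power, x$ratio))
  cat(sprintf("  n1 = %d, n2 = %d, total = %d\n", x$n1, x$n2, x$n_t))
  cat(sprintf("  achieved power = %.*f\n", digits, x$achieved_power))
  invisible(x)
}
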