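#' Per-group sufficient statistics for a simple linear regression
#'
#' A `group_summary` holds everything the slope-comparison procedures need
#' from one treatment group: the sample size, the least-squares slope and
#' intercept, the centered predictor sum of squares SSX, the residual sum
#' of squares SSE, and the unbiased error-variance estimate SSE/(n - 2).
#' Summaries can be computed from raw data with [summarize_group()] or
#' assembled directly from published statistics with [group_summary()],
#' so an analysis reported only through its summary numbers remains
#' exactly reproducible.
#'
#' @param n sample size (integer, at least 3).
#' @param slope least-squares slope estimate.
#' @param ssx centered sum of squares of the predictor,
#'   \eqn{\sum (x - \bar x)^2}; strictly positive.  Exactly one of `ssx`
#'   and `tau2` must be given.
#' @param tau2 sample variance of the predictor, `ssx / (n - 1)`.
#'   Convenient when a report prints the predictor variance rather than
#'   SSX.
#' @param sigma2 unbiased error-variance estimate SSE/(n - 2).  Exactly
#'   one of `sigma2` and `sse` must be given.
#' @param sse residual sum of squares.
#' @param intercept least-squares intercept (optional; not used by the
#'   slope tests).
#' @param xbar predictor sample mean (optional; not used by the slope
#'   tests).
#' @param label group identifier used in printing.
#'
#' @return An object of class `"group_summary"`: a list with components
#'   `n`, `slope`, `intercept`, `ssx`, `sse`, `sigma2`, `xbar`, `c`
#'   (residual degrees of freedom, `n - 2`) and `label`.
#'
#' @examples
#' ## a group known only through its published summary statistics
#' g <- group_summary(n = 9, slope = 15.9286, tau2 = 31.1111,
#'                    sigma2 = 10124.8980)
#' g$ssx      # (n - 1) * tau2
#'
#' @seealso [summarize_group()], [welch_slope_test()]
#' @export
group_summary <- function(n, slope, ssx = NULL, tau2 = NULL,
                          sigma2 = NULL, sse = NULL,
                          intercept = NA_real_, xbar = NA_real_,
                          label = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 3L)
    stop("'n' must be a single integer >= 3 (need at least one residual ",
         "degree of freedom)", call. = FALSE)
  if (is.null(ssx) == is.null(tau2))
    stop("supply exactly one of 'ssx' and 'tau2'", call. = FALSE)
  if (is.null(ssx)) ssx <- (n - 1) * tau2
  if (!is.finite(ssx) || ssx <= 0)
    stop("'ssx' must be strictly positive (the predictor must vary)",
         call. = FALSE)
  if (is.null(sigma2) == is.null(sse))
    stop("supply exactly one of 'sigma2' and 'sse'", call. = FALSE)
  cdf <- n - 2L
  if (is.null(sigma2)) sigma2 <- sse / cdf else sse <- sigma2 * cdf
  if (!is.finite(sigma2) || sigma2 < 0)
    stop("error variance must be non-negative", call. = FALSE)
  structure(
    list(n = n, slope = as.numeric(slope), intercept = as.numeric(intercept),
         ssx = as.numeric(ssx), sse = as.numeric(sse),
         sigma2 = as.numeric(sigma2), xbar = as.numeric(xbar),
         c = cdf, label = label),
    class = "group_summary")
}

#' Summarize one group's raw data
#'
#' Fits the within-group simple linear regression by ordinary least
#' squares and returns the sufficient statistics consumed by
#' [welch_slope_test()] and [pooled_slope_test()].
#'
#' @param x numeric predictor values (at least 3, not all equal).
#' @param y numeric responses, same length as `x`.
#' @param label optional group identifier.
#'
#' @return A [group_summary()] object.
#'
#' @examples
#' set.seed(1)
#' x <- rnorm(20, mean = 40, sd = 6)
#' y <- 2 + 1.5 * x + rnorm(20, sd = 4)
#' summarize_group(x, y)
#'
#' @export
summarize_group <- function(x, y, label = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values in 'x' or 'y'", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 observations per group (n - 2 residual ",
         "degrees of freedom)", call. = FALSE)
  ssx <- sum((x - mean(x))^2)
  if (ssx <= 0)
    stop("degenerate predictor: all x values are equal (SSX = 0)",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  group_summary(n = n,
                slope = unname(b[2L]),
                ssx = ssx,
                sse = sum(stats::residuals(fit)^2),
                intercept = unname(b[1L]),
                xbar = mean(x),
                label = label)
}

#' @export
print.group_summary <- function(x, digits = 4L, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat("Group regression summary", lab, "\n", sep = "")
  cat(sprintf("  n = %d, slope = %.*f, SSX = %.*f\n",
              x$n, digits, x$slope, digits, x$ssx))
  cat(sprintf("  SSE = %.*f, error variance = %.*f (df = %d)\n",
              digits, x$sse, digits, x$sigma2, x$c))
  invisible(x)
}

is_group_summary <- function(x) inherits(x, "group_summary")

assert_group_summary <- function(x, arg) {
  if (!is_group_summary(x))
    stop("'", arg, "' must be a 'group_summary' (see group_summary() or ",
         "summarize_group())", call. = FALSE)
  invisible(x)
}

#' Read two-group raw data from CSV
#'
#' Reads a comma-separated file with header `group,x,y`, where `group`
#' takes exactly two values (conventionally 1 and 2), and returns the two
#' per-group regression summaries.  Malformed rows are reported with
#' their line numbers.
#'
#' @param path path to the CSV file.
#'
#' @return A list of two [group_summary()] objects, ordered by the sorted
#'   unique group labels.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' set.seed(7)
#' d <- data.frame(group = rep(1:2, c(10, 15)),
#'                 x = rnorm(25), y = rnorm(25))
#' write.csv(d, tf, row.names = FALSE)
#' read_two_groups(tf)
#'
#' @export
read_two_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "x", "y")
  if (!all(need %in% names(d)))
    stop("CSV must have columns 'group', 'x' and 'y' (found: ",
         paste(names(d), collapse = ", "), ")", call. = FALSE)
  # +1 header line so reported numbers match the file
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$x))) |
               !is.finite(suppressWarnings(as.numeric(d$y))))
  if (length(bad))
    stop("non-numeric or missing x/y on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  labs <- sort(unique(d$group))
  if (length(labs) != 2L)
    stop("expected exactly 2 groups, found ", length(labs), ": ",
         paste(labs, collapse = ", "), call. = FALSE)
  lapply(labs, function(g) {
    rows <- d$group == g
    summarize_group(as.numeric(d$x[rows]), as.numeric(d$y[rows]),
                    label = as.character(g))
  })
}
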