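#' Pearson correlation with a two-tailed t-test
#'
#' Product-moment correlation between a surrogate marker and a
#' functional readout, with significance from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-tailed. Perfect correlations (|r| = 1 to floating tolerance) are
#' reported with `p = 0`. Pairs with a missing member are dropped
#' listwise with a warning.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 after dropping
#'   incomplete pairs.
#' @return Object of class `correlation_result`: `r`, `n`,
#'   `t_statistic`, `degrees_of_freedom`, `p_two_tailed`.
#' @export
#' @examples
#' p <- simulate_correlated_pairs(10, rho = -0.9, seed = 1)
#' pearson_with_t_test(p$surrogate, p$functional)
pearson_with_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    warning(sum(!ok), " incomplete pair(s) dropped listwise")
    x <- x[ok]; y <- y[ok]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  if (1 - r^2 < .Machine$double.eps) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r = r, n = n, t_statistic = t, degrees_of_freedom = df,
                 p_two_tailed = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4g (n = %d)\n", x$r, x$n))
  cat(sprintf("  t = %.4g on %d df, two-tailed p = %.3g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_tailed))
  invisible(x)
}

#' Linear cross-platform calibration
#'
#' Ordinary least-squares regression of one platform's measurements on
#' another's (e.g. CD63 ELISA concentration against nanoparticle
#' tracking counts), with the Pearson correlation as the agreement
#' summary.
#'
#' @param reference Predictor platform values.
#' @param measured Response platform values.
#' @return Object of class `calibration_fit`: `slope`, `intercept`,
#'   `r`, `n`, and the underlying `lm` fit as `model`.
#' @export
#' @examples
#' calibration_fit(1:3, c(2, 4, 6))
calibration_fit <- function(reference, measured) {
  stopifnot(is.numeric(reference), is.numeric(measured))
  if (length(reference) != length(measured))
    stop("vectors must have equal length", call. = FALSE)
  ok <- is.finite(reference) & is.finite(measured)
  if (!all(ok)) {
    warning(sum(!ok), " incomplete pair(s) dropped listwise")
    reference <- reference[ok]; measured <- measured[ok]
  }
  if (length(reference) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(reference) == 0)
    stop("zero variance in the reference platform", call. = FALSE)
  m <- stats::lm(measured ~ reference)
  structure(list(slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 r = stats::cor(reference, measured),
                 n = length(reference),
                 model = m),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: measured = %.4g + %.4g * reference  (r = %.4g, n = %d)\n",
              x$intercept, x$slope, x$r, x$n))
  invisible(x)
}
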