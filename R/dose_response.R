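#' Fit a four-parameter logistic inhibition curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' to normalized proliferation responses versus MSC dose, parameterized
#' on log10(dose) with the hill slope constrained positive (inhibition
#' curves decrease with dose). Five Levenberg-Marquardt starts are tried
#' from data-driven heuristics (top = max response, bottom = min
#' response, IC50 at the dose nearest mid-response or at the geometric
#' mean dose, hill in {0.5, 1, 2}); the lowest residual sum of squares
#' wins, ties going to the first start.
#'
#' @param dose MSC cell counts (positive).
#' @param response Normalized replication indices (control = 1).
#' @param fixed_top,fixed_bottom Optionally pin an asymptote instead of
#'   estimating it.
#' @param flat_tol Responses with sample SD below this are rejected as
#'   unidentifiable (default 1e-3 on the normalized scale).
#' @return Object of class `dose_response_fit`: `top`, `bottom`,
#'   `ic50_relative` (dose at the curve midpoint), `hill_slope`,
#'   `ic50_absolute` (dose where the fitted curve crosses 0.5, `NA` if
#'   unreachable), `residual_sum_of_squares`, `converged`, `n`, `data`.
#' @export
#' @examples
#' dr <- simulate_suppression_series(noise_sd = 0, n_replicates = 1)
#' fit_inhibition_curve(dr$dose, dr$response)
fit_inhibition_curve <- function(dose, response,
                                 fixed_top = NULL, fixed_bottom = NULL,
                                 flat_tol = 1e-3) {
  stopifnot(length(dose) == length(response))
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose <= 0)) stop("doses must be > 0", call. = FALSE)
  n_free <- 4L - !is.null(fixed_top) - !is.null(fixed_bottom)
  if (length(unique(dose)) < n_free)
    stop("need at least as many distinct doses as free parameters (",
         n_free, ")", call. = FALSE)
  if (stats::sd(response) < flat_tol)
    stop("unidentifiable fit: response is flat (sd < ", flat_tol, ")",
         call. = FALSE)

  ld <- log10(dose)
  top0 <- if (is.null(fixed_top)) max(response) else fixed_top
  bot0 <- if (is.null(fixed_bottom)) min(response) else fixed_bottom
  mid <- (top0 + bot0) / 2
  li_mid <- ld[which.min(abs(response - mid))]
  li_geo <- mean(ld)
  starts <- list(c(li = li_mid, hill = 0.5), c(li = li_mid, hill = 1),
                 c(li = li_mid, hill = 2),  c(li = li_geo, hill = 1),
                 c(li = li_geo, hill = 2))

  fits <- lapply(starts, function(s) {
    start <- list(li = unname(s["li"]), hill = unname(s["hill"]))
    lower <- c(li = min(ld) - 3, hill = 1e-3)
    upper <- c(li = max(ld) + 3, hill = 50)
    form <- response ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - li)))
    env <- list(ld = ld, response = response)
    if (is.null(fixed_top)) {
      start$top <- top0
      lower <- c(lower, top = -Inf); upper <- c(upper, top = Inf)
    } else env$top <- fixed_top
    if (is.null(fixed_bottom)) {
      start$bottom <- bot0
      lower <- c(lower, bottom = -Inf); upper <- c(upper, bottom = Inf)
    } else env$bottom <- fixed_bottom
    tryCatch({
      m <- minpack.lm::nlsLM(form, data = env, start = start,
                             lower = lower[names(start)],
                             upper = upper[names(start)],
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
      list(model = m, rss = sum(stats::residuals(m)^2),
           converged = m$convInfo$isConv)
    }, error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("all optimization starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]

  cf <- stats::coef(best$model)
  top <- if (is.null(fixed_top)) unname(cf["top"]) else fixed_top
  bottom <- if (is.null(fixed_bottom)) unname(cf["bottom"]) else fixed_bottom
  fit <- structure(list(
    top = top, bottom = bottom,
    ic50_relative = 10^unname(cf["li"]),
    hill_slope = unname(cf["hill"]),
    residual_sum_of_squares = best$rss,
    converged = isTRUE(best$converged),
    n = length(dose),
    data = data.frame(dose = dose, response = response)
  ), class = "dose_response_fit")
  fit$ic50_absolute <- ic50_from_fit(fit, level = 0.5, check_converged = FALSE)
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter logistic inhibition fit\n")
  cat(sprintf("  top       %.4g\n  bottom    %.4g\n", x$top, x$bottom))
  cat(sprintf("  IC50 (relative, curve midpoint): %.4g\n", x$ic50_relative))
  if (is.na(x$ic50_absolute)) {
    cat("  IC50 (absolute, response = 0.5): not reached\n")
  } else {
    cat(sprintf("  IC50 (absolute, response = 0.5): %.4g\n", x$ic50_absolute))
  }
  cat(sprintf("  hill slope %.4g   RSS %.4g   n = %d   converged: %s\n",
              x$hill_slope, x$residual_sum_of_squares, x$n, x$converged))
  invisible(x)
}

#' Predict from a fitted inhibition curve
#'
#' @param object A `dose_response_fit`.
#' @param newdata Optional data frame with a `dose` column (defaults to
#'   the fitted data).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else newdata$dose
  four_param_logistic(d, object$top, object$bottom, object$ic50_relative,
                      object$hill_slope)
}

#' Absolute IC50: dose at which the fitted curve crosses a response level
#'
#' Solves `fitted(dose) = level` in closed form:
#' `ic50_relative * ((top - level)/(level - bottom))^(1/hill)`. With the
#' default `level = 0.5` on a control-normalized scale this is the MSC
#' dose inhibiting proliferation by 50%. When the level lies outside
#' `(bottom, top)` the curve never crosses it and `NA` is returned with
#' a `reason` attribute (not an error: an incomplete curve is a
#' diagnostic, not a defect).
#'
#' @param fit A `dose_response_fit`.
#' @param level Response level to cross (default 0.5).
#' @param check_converged Error when the fit did not converge (default
#'   TRUE).
#' @return Dose (MSC cell count), or `NA` when the level is unreachable.
#' @export
ic50_from_fit <- function(fit, level = 0.5, check_converged = TRUE) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (check_converged && !fit$converged)
    stop("fit did not converge; absolute IC50 not meaningful", call. = FALSE)
  if (!(level > fit$bottom && level < fit$top)) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "level %.3g outside the fitted response range (%.3g, %.3g)",
      level, fit$bottom, fit$top)
    return(out)
  }
  fit$ic50_relative *
    ((fit$top - level) / (level - fit$bottom))^(1 / fit$hill_slope)
}

#' Fold difference between two IC50s
#'
#' `ic50_b / ic50_a`: values above 1 mean condition (or donor) `a`
#' reaches half-inhibition at a lower dose, i.e. is the more potent.
#'
#' @param ic50_a,ic50_b Positive IC50s on the same dose units.
#' @return Dimensionless fold difference.
#' @export
#' @examples
#' fold_difference(1000, 2600)  # 2.6
fold_difference <- function(ic50_a, ic50_b) {
  if (any(c(ic50_a, ic50_b) <= 0) || any(!is.finite(c(ic50_a, ic50_b))))
    stop("IC50s must be positive and finite", call. = FALSE)
  ic50_b / ic50_a
}
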