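#' Per-factor summary statistics and quartile breakpoints
#'
#' Mean, sample SD (n-1 denominator), coefficient of variation (CV,
#' percent) and the three quartile breakpoints of one potency factor
#' across the donor panel. Quartiles use linear interpolation between
#' order statistics, placing the p-quantile of n sorted values at
#' position `1 + (n - 1) * p` (R's default, `stats::quantile` type 7);
#' the convention is configurable via `quartile_type` because quartile
#' membership of edge donors in small panels can depend on it.
#'
#' @param x Numeric factor values across donors, or a donor panel data
#'   frame (then `factor_name` selects the column).
#' @param factor_name Column to summarize when `x` is a data frame.
#' @param quartile_type Quantile algorithm, passed to
#'   [stats::quantile()] (default 7).
#' @return Object of class `factor_stats`: `factor_name`, `n`, `mean`,
#'   `sd`, `cv_percent`, `q1`, `q2`, `q3`, `quartile_type`.
#' @export
#' @examples
#' factor_stats(1:8)          # q1 2.75, q2 4.5, q3 6.25
#' factor_stats(c(2, 4, 6))   # mean 4, sd 2, cv 50%
factor_stats <- function(x, factor_name = NULL, quartile_type = 7) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(factor_name), factor_name %in% names(x))
    x <- x[[factor_name]]
  }
  x <- x[is.finite(x)]
  if (length(x) < 2)
    stop("need at least 2 finite values per factor", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined: factor mean is zero", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  structure(list(factor_name = if (is.null(factor_name)) NA_character_
                               else factor_name,
                 n = length(x), mean = m, sd = stats::sd(x),
                 cv_percent = 100 * stats::sd(x) / m,
                 q1 = q[1], q2 = q[2], q3 = q[3],
                 quartile_type = quartile_type),
            class = "factor_stats")
}

#' @export
print.factor_stats <- function(x, ...) {
  cat(sprintf("Factor %s: n = %d, mean = %.4g, sd = %.4g, CV = %.1f%%\n",
              x$factor_name, x$n, x$mean, x$sd, x$cv_percent))
  cat(sprintf("  quartiles (type %d): q1 = %.4g, q2 = %.4g, q3 = %.4g\n",
              x$quartile_type, x$q1, x$q2, x$q3))
  invisible(x)
}

#' Assign 0-3 quartile points to measurements
#'
#' The potency matrix's scoring rule: 0 points below the first quartile,
#' 1 point in `[q1, q2)`, 2 in `[q2, q3)`, 3 at or above the third
#' quartile. Bins are half-open with breakpoint-equal values promoted to
#' the higher bin, which guarantees the panel maximum always scores 3
#' and the minimum 0. Values outside the panel range still map to 0
#' or 3.
#'
#' @param value Measurement(s) on the factor's scale (vectorized).
#' @param stats A `factor_stats` object for that factor.
#' @return Integer points in `{0, 1, 2, 3}`.
#' @export
#' @examples
#' s <- factor_stats(1:8)
#' assign_points(c(1, 5, 8), s)  # 0, 2, 3
assign_points <- function(value, stats) {
  stopifnot(inherits(stats, "factor_stats"))
  if (any(!is.finite(value)))
    stop("values must be finite", call. = FALSE)
  findInterval(value, c(stats$q1, stats$q2, stats$q3))
}

#' Factor-weight presets for the potency matrix
#'
#' * `"unit"` - all factors weighted 1 (the unweighted matrix).
#' * `"methods"` - IDO1 and CD63 scores doubled, CCL2 halved, M-CSF
#'   unchanged: weights (IDO1 2, MCSF 1, CD63 2, CCL2 0.5). The default
#'   weighted preset.
#' * `"results"` - an alternative in which M-CSF is also doubled:
#'   (IDO1 2, MCSF 2, CD63 2, CCL2 0.5). Shipped because source
#'   descriptions of the weighting differ on M-CSF; choose explicitly
#'   when it matters.
#'
#' @param preset One of `"unit"`, `"methods"`, `"results"`.
#' @return Named numeric weight vector.
#' @export
potency_weights <- function(preset = c("unit", "methods", "results")) {
  switch(match.arg(preset),
         unit    = c(IDO1 = 1, MCSF = 1, CD63 = 1, CCL2 = 1),
         methods = c(IDO1 = 2, MCSF = 1, CD63 = 2, CCL2 = 0.5),
         results = c(IDO1 = 2, MCSF = 2, CD63 = 2, CCL2 = 0.5))
}

#' Score a donor panel: the potency matrix
#'
#' For each factor, computes panel-wide quartiles ([factor_stats()]) and
#' assigns each donor 0-3 points ([assign_points()]); totals the points
#' per donor, unweighted and with per-factor weights. Donors missing a
#' value for any scored factor are excluded from that factor's quartiles
#' and receive `NA` totals, with a warning (no imputation).
#'
#' @param panel Donor panel data frame: `donor_id` plus one numeric
#'   column per factor (see [simulate_donor_panel()] or
#'   [read_donor_panel()]).
#' @param weights Named per-factor weights (positive), a preset name
#'   understood by [potency_weights()], or `NULL` for unit weights.
#'   Every name must be a scored factor.
#' @param factors Factor columns to score (default: all numeric columns
#'   except `donor_id`).
#' @param quartile_type Quantile convention, see [factor_stats()].
#' @return Data frame of class `potency_score`: `donor_id`, one
#'   `<factor>_points` column per factor, `unweighted_total`,
#'   `weighted_total`. Attributes: `factor_stats` (list), `weights`.
#' @export
#' @examples
#' panel <- simulate_donor_panel(8, seed = 1)
#' score_panel(panel, weights = "methods")
score_panel <- function(panel, weights = NULL, factors = NULL,
                        quartile_type = 7) {
  stopifnot(is.data.frame(panel), "donor_id" %in% names(panel))
  if (anyDuplicated(panel$donor_id))
    stop("donor_ids must be unique", call. = FALSE)
  if (is.null(factors))
    factors <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
                       "donor_id")
  if (length(factors) == 0) stop("no factor columns to score", call. = FALSE)
  if (is.character(weights) && length(weights) == 1)
    weights <- potency_weights(weights)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(factors)),
                                                   factors)
  if (is.null(names(weights)) || !all(names(weights) %in% factors))
    stop("weights must be named after scored factors; unknown: ",
         paste(setdiff(names(weights), factors), collapse = ", "),
         call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  w <- stats::setNames(rep(1, length(factors)), factors)
  w[names(weights)] <- weights

  stats_list <- list()
  pts <- matrix(NA_integer_, nrow(panel), length(factors),
                dimnames = list(panel$donor_id, factors))
  for (f in factors) {
    v <- panel[[f]]
    fs <- factor_stats(v[is.finite(v)], factor_name = f,
                       quartile_type = quartile_type)
    stats_list[[f]] <- fs
    pts[is.finite(v), f] <- assign_points(v[is.finite(v)], fs)
  }
  incomplete <- rowSums(is.na(pts)) > 0
  if (any(incomplete))
    warning("donor(s) excluded from totals for missing factor values: ",
            paste(panel$donor_id[incomplete], collapse = ", "))

  out <- data.frame(donor_id = panel$donor_id, stringsAsFactors = FALSE)
  for (f in factors) out[[paste0(f, "_points")]] <- pts[, f]
  out$unweighted_total <- ifelse(incomplete, NA_real_, rowSums(pts))
  out$weighted_total <- ifelse(incomplete, NA_real_,
                               as.vector(pts %*% w[factors]))
  attr(out, "factor_stats") <- stats_list
  attr(out, "weights") <- w
  class(out) <- c("potency_score", "data.frame")
  out
}

#' Rank donors by potency score
#'
#' Orders donors by descending total (weighted or unweighted).
#' Ties receive the same competition (minimum) rank; row order is
#' deterministic, by descending total then donor_id. Donors with `NA`
#' totals sort last with `NA` rank.
#'
#' @param scores A `potency_score` data frame from [score_panel()].
#' @param by `"weighted"` or `"unweighted"`.
#' @return The scores with a `rank` column, reordered.
#' @export
#' @examples
#' panel <- simulate_donor_panel(8, seed = 1)
#' rank_donors(score_panel(panel), by = "unweighted")
rank_donors <- function(scores, by = c("weighted", "unweighted")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0) stop("no donors to rank", call. = FALSE)
  total <- scores[[paste0(by, "_total")]]
  rk <- rep(NA_integer_, length(total))
  ok <- !is.na(total)
  rk[ok] <- as.integer(rank(-total[ok], ties.method = "min"))
  scores$rank <- rk
  ord <- order(!ok, -ifelse(ok, total, -Inf), scores$donor_id)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
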