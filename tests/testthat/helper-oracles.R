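# Independent oracles, deliberately written from first principles so they
# share no code path with the implementation they check.

# Pearson r, t and two-tailed p by explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# Two-pass CV (fraction): sample SD over mean.
oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

# Quartile points by direct rank counting on a tie-free panel whose size
# is divisible by 4: ranks 1..n/4 -> 0 points, ..., last n/4 -> 3.
oracle_points_by_rank <- function(values) {
  n <- length(values)
  stopifnot(n %% 4 == 0, !anyDuplicated(values))
  as.integer(floor((rank(values) - 1) / (n / 4)))
}

# Dose where the 4PL crosses `level`, by bisection-free dense grid scan.
oracle_ic50_grid <- function(top, bottom, ic50, hill, level = 0.5,
                             n_grid = 2e5) {
  ld <- seq(log10(ic50) - 4, log10(ic50) + 4, length.out = n_grid)
  resp <- four_param_logistic(10^ld, top, bottom, ic50, hill)
  i <- which.min(abs(resp - level))
  10^ld[i]
}

# Replication index straight from a count vector (generations 0..G).
oracle_ri <- function(counts) {
  g <- seq_along(counts) - 1
  divided <- sum(counts[g >= 1])
  prec <- sum(counts[g >= 1] / 2^g[g >= 1])
  if (prec > 0) divided / prec else 1
}

truth_counts <- function(events, max_gen = 8) {
  as.vector(table(factor(events$true_generation, levels = 0:max_gen)))
}
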