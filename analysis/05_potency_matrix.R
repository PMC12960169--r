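#!/usr/bin/env Rscript
# The headline analysis: per-factor summary statistics, the quartile
# 0-3 point matrix, weighted totals and donor ranks.

suppressPackageStartupMessages(library(mscpotency))
panel <- read_donor_panel("results/donor_panel.csv")

fstats <- do.call(rbind, lapply(setdiff(names(panel), "donor_id"), function(f) {
  s <- factor_stats(panel, f)
  data.frame(factor = f, n = s$n, mean = s$mean, sd = s$sd,
             cv_percent = s$cv_percent, q1 = s$q1, q2 = s$q2, q3 = s$q3)
}))
utils::write.csv(fstats, "results/factor_stats.csv", row.names = FALSE)
cat("per-factor panel statistics:\n")
print(fstats, row.names = FALSE, digits = 3)

unweighted <- rank_donors(score_panel(panel), by = "unweighted")
weighted <- rank_donors(score_panel(panel, weights = "methods"),
                        by = "weighted")
utils::write.csv(unweighted, "results/potency_matrix_unweighted.csv",
                 row.names = FALSE)
utils::write.csv(weighted, "results/potency_matrix_weighted.csv",
                 row.names = FALSE)

cat("\nunweighted matrix (0-3 points per factor):\n")
print(unweighted, row.names = FALSE)
cat("\nweighted matrix (IDO1 x2, CD63 x2, CCL2 x0.5):\n")
print(weighted, row.names = FALSE)
cat(sprintf("\ntop-ranked donor (weighted): %s\n", weighted$donor_id[1]))
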