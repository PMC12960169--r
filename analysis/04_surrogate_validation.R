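#!/usr/bin/env Rscript
# Validate the surrogate potency marker against the functional readout:
# Pearson correlation with a two-tailed t-test at the 10-donor design
# scale, plus a linear cross-platform calibration example.

suppressPackageStartupMessages(library(mscpotency))
pairs <- utils::read.csv("results/surrogate_pairs.csv")

res <- pearson_with_t_test(pairs$pct_ido1_pos, pairs$replication_index)
print(res)

# cross-platform calibration: simulate an ELISA-vs-particle-count pair
# with a strong linear relation and recover the line
set.seed(202)
nta <- runif(24, 1e11, 9e11)                  # particles/mL
elisa <- 2e-11 * nta + rnorm(24, 0, 3)        # ng/mL
cal <- calibration_fit(nta, elisa)
print(cal)

out <- data.frame(
  comparison = c("pct_ido1_pos~replication_index", "elisa~nta"),
  r = c(res$r, cal$r),
  p_two_tailed = c(res$p_two_tailed,
                   pearson_with_t_test(nta, elisa)$p_two_tailed),
  n = c(res$n, cal$n))
utils::write.csv(out, "results/surrogate_validation.csv", row.names = FALSE)
cat(sprintf("surrogate correlation r = %.2f (p = %.2g, n = %d)\n",
            res$r, res$p_two_tailed, res$n))
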