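#!/usr/bin/env Rscript
# Fit four-parameter logistic inhibition curves per donor and compare
# potency by the fold difference of absolute IC50s.

suppressPackageStartupMessages(library(mscpotency))
dr <- read_dose_response("results/dose_response.csv")

fits <- lapply(split(dr, dr$donor), function(d)
  fit_inhibition_curve(d$dose, d$response))

tab <- do.call(rbind, lapply(names(fits), function(dn) {
  f <- fits[[dn]]
  data.frame(donor = dn, top = f$top, bottom = f$bottom,
             ic50_relative = f$ic50_relative,
             ic50_absolute = f$ic50_absolute,
             hill_slope = f$hill_slope,
             rss = f$residual_sum_of_squares, converged = f$converged)
}))
utils::write.csv(tab, "results/ic50_fits.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)

fd <- fold_difference(fits$donor_A$ic50_absolute, fits$donor_B$ic50_absolute)
cat(sprintf("donor_A reaches half-inhibition at a %.2f-fold lower MSC dose than donor_B\n",
            fd))
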