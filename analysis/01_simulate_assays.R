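#!/usr/bin/env Rscript
# Generate the synthetic assay inputs used by the downstream analyses:
# an 8-donor potency-factor panel, CFSE event tables for a suppression
# co-culture and its stimulated control, dose-response series for two
# donors of different potency, and surrogate/functional pairs for 10
# donors. Everything is written under results/ as plain CSV.

suppressPackageStartupMessages(library(mscpotency))
dir.create("results", showWarnings = FALSE)
set.seed(101)

cfg <- sim_config(seed = 101)
write_sim_config(cfg, "results/sim_config.yaml")

# 8-donor panel with the observed between-donor CVs
panel <- simulate_donor_panel(cfg$n_donors, cfg$factor_specs)
write_donor_panel(panel, "results/donor_panel.csv",
                  units = c(IDO1 = "% IDO1+ cells", MCSF = "pg/mL",
                            CD63 = "ng/mL", CCL2 = "pg/mL"))
cat(sprintf("donor panel: %d donors x %d factors; CVs (%%): %s\n",
            nrow(panel), ncol(panel) - 1,
            paste(sprintf("%s %.1f", names(panel)[-1],
                          100 * vapply(panel[-1], cv_fraction, 0)),
                  collapse = ", ")))

# CFSE events: stimulated control proliferates hard, the MSC co-culture
# is pushed back toward early generations
ctrl <- simulate_cfse_events(cfg$cfse_spec$n_events,
                             generation_probs = c(0.1, 0.08, 0.12, 0.2,
                                                  0.25, 0.17, 0.08),
                             condition = "stim_control")
cocx <- simulate_cfse_events(cfg$cfse_spec$n_events,
                             generation_probs = c(0.55, 0.2, 0.12,
                                                  0.08, 0.05),
                             condition = "msc_coculture")
write_event_table(rbind(ctrl, cocx), "results/cfse_events.csv")
cat(sprintf("CFSE events: %d per condition (2 conditions)\n", nrow(ctrl)))

# dose-response series: a potent and a less potent donor (true IC50s
# 5e3 vs 1.3e4 MSCs, a 2.6-fold difference)
doses <- 10^seq(3, 5, length.out = 8)
dr_a <- simulate_suppression_series(doses, ic50 = 5e3, noise_sd = 0.05)
dr_b <- simulate_suppression_series(doses, ic50 = 1.3e4, noise_sd = 0.05)
dr_a$donor <- "donor_A"; dr_b$donor <- "donor_B"
write_dose_response(rbind(dr_a, dr_b), "results/dose_response.csv")

# surrogate vs functional readout across 10 donors (IDO1-like design)
pairs <- simulate_correlated_pairs(10, rho = -0.9,
                                   means = c(50, 2), sds = c(20, 0.4))
names(pairs) <- c("pct_ido1_pos", "replication_index")
utils::write.csv(pairs, "results/surrogate_pairs.csv", row.names = FALSE)
cat("wrote results/: donor_panel, cfse_events, dose_response, surrogate_pairs\n")
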