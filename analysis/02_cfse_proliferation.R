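#!/usr/bin/env Rscript
# CFSE dye-dilution analysis: bin events into division generations,
# compute proliferation statistics per condition, and normalize the MSC
# co-culture to the stimulated control.

suppressPackageStartupMessages(library(mscpotency))
ev <- read_event_table("results/cfse_events.csv")

gen0 <- estimate_gen0_center(ev$fluorescence)
cat(sprintf("estimated generation-0 centre: %.0f (a.u.)\n", gen0))

profile <- bin_events_to_generations(ev, gen0_center = gen0)
utils::write.csv(profile, "results/generation_profile.csv", row.names = FALSE)

stats_by <- lapply(split(profile, profile$condition), proliferation_stats)
tab <- do.call(rbind, lapply(names(stats_by), function(cn) {
  s <- stats_by[[cn]]
  data.frame(condition = cn, replication_index = s$replication_index,
             division_index = s$division_index,
             percent_divided = s$percent_divided)
}))
tab$normalized_ri <- vapply(stats_by, normalize_to_control,
                            numeric(1), control = stats_by$stim_control)
utils::write.csv(tab, "results/proliferation_stats.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("MSC co-culture suppressed proliferation to %.0f%% of control\n",
            100 * tab$normalized_ri[tab$condition == "msc_coculture"]))
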