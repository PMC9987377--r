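#!/usr/bin/env Rscript
# Stage 4: the six survey LMMs (per-instrument trajectories, combined
# staff/self-entry ALSFRS with indicator + interaction, device-group
# comparisons) and the +/- 28-day matched Pearson correlations.

suppressMessages(library(alswear))
suppressMessages(library(data.table))
cohort <- readRDS("scratch/cohort.rds")

traj <- fit_trajectory_models(cohort$surveys)
combined <- fit_combined_scale_model(cohort$surveys)
devgrp <- fit_device_group_models(cohort$surveys, cohort$profiles)
correlations <- matched_pearson(cohort$surveys)

row <- function(f, nm) data.table(model = nm, f$fixed, r2m = f$r2m, r2c = f$r2c)
fits <- rbindlist(c(
  lapply(names(traj), function(nm) row(traj[[nm]], nm)),
  list(row(combined, "combined_alsfrs")),
  lapply(names(devgrp), function(nm) row(devgrp[[nm]], paste0("device_", nm)))))

write_table_csv(fits, "results/survey_model_estimates.csv")
write_table_csv(correlations, "results/matched_correlations.csv")
cond <- rbindlist(lapply(names(traj), function(nm)
  data.table(instrument = nm, traj[[nm]]$conditional)))
write_table_csv(cond, "results/survey_conditional_means.csv")

for (nm in names(traj)) {
  est <- traj[[nm]]$fixed
  cat(sprintf("%-11s baseline %6.2f, slope %6.3f/month\n", nm,
              est$estimate[est$term == "(Intercept)"],
              est$estimate[est$term == "t_months"]))
}
cat(sprintf("self-entry offset: %.2f points\n",
            combined$fixed$estimate[combined$fixed$term == "self_entry"]))
print(correlations)
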