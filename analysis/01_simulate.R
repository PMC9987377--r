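#!/usr/bin/env Rscript
# Stage 1: simulate the default cohort — 40 ambulatory participants followed
# for 180 days, 20 wearing the wrist activity-count device and 20 the ankle
# step-count device, surveyed by smartphone every 2-4 weeks with staff
# ALSFRS-R at months 0/3/6. Minute-level streams go to scratch/ (large);
# small summaries to results/.

suppressMessages(library(alswear))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(master_seed = 20230306L)
cohort <- generate_cohort(cfg)
print(cohort)

saveRDS(cfg, "scratch/config.rds")
saveRDS(cohort, "scratch/cohort.rds")
write_survey_csv(cohort$surveys, "scratch/surveys.csv")
write_table_csv(cohort$profiles, "scratch/participant_truth.csv")

cat(sprintf("surveys: %d observations; self-entry events per participant: %.1f on average\n",
            nrow(cohort$surveys),
            nrow(cohort$surveys[cohort$surveys$instrument == "alsfrs_rse", ]) /
              cfg$n_participants))
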