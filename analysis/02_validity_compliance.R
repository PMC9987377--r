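#!/usr/bin/env Rscript
# Stage 2: classify valid hours/days per device (actigraph: 60 worn,
# non-missing minutes per clock hour; modus: >= 1 step per hour; valid day
# >= 8 valid hours) and summarize wear and survey compliance.

suppressMessages(library(alswear))
cohort <- readRDS("scratch/cohort.rds")

flt <- filter_valid_days(cohort$wearable)
compliance <- compliance_summary(flt$validity, cohort$surveys)

saveRDS(flt, "scratch/filtered.rds")
write_table_csv(flt$validity, "scratch/day_validity.csv")
write_table_csv(compliance, "results/compliance_summary.csv")

cat(sprintf("valid days: %d of %d participant-days\n",
            sum(flt$validity$is_valid_day), nrow(flt$validity)))
print(compliance)
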