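#!/usr/bin/env Rscript
# Stage 6: association LMMs. Each survey score is modelled on the
# standardized 15-day window mean (7 days either side of the survey) of a
# daily measure, with participant random intercept and random slope on the
# covariate; a measure counts as robustly associated when significant for
# both self-entry instruments.

suppressMessages(library(alswear))
cohort <- readRDS("scratch/cohort.rds")
daily <- readRDS("scratch/daily_measures.rds")

surveys <- analysis_sample(cohort$surveys)
surveys <- surveys[surveys$instrument %in% c("alsfrs_rse", "roads"), ]
covariates <- build_covariates(daily, surveys)
associations <- fit_associations(covariates)

write_table_csv(associations, "results/association_estimates.csv")

both <- unique(associations$measure[associations$significant_both])
cat(sprintf("%d of %d measures significantly associated with both surveys:\n",
            length(both), length(unique(associations$measure))))
cat(" ", paste(sort(both), collapse = ", "), "\n")
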