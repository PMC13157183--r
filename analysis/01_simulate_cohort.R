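#!/usr/bin/env Rscript
# Step 1 -- simulate the neonatal cohort.
#
# Generates the synthetic analogue of the clinical material: 89 neonates in
# four developmental-age strata (34 at or below 37 weeks, 27 in 37-41, 16 in
# 41-49, 12 over 49), each with an IEF-PAGE lane whose hepatic/renal band
# mixture follows the maturation logistic (midpoint 43 weeks, slope 0.5 per
# week), plus the two recombinant-drug calibration lanes.

suppressMessages(library(eposwitch))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- cohort_sim_params(seed = 20260927L)
cohort <- simulate_cohort(params)

write_cohort(cohort$records, file.path(out_dir, "cohort.csv"))
write_lanes(cohort$lanes, file.path(out_dir, "lanes.tsv"))
write_lanes(cohort$reference, file.path(out_dir, "reference_lanes.tsv"))

cat(sprintf("simulated %d subjects (%s per stratum)\n",
            nrow(cohort$records),
            paste(table(cohort$records$group), collapse = "/")))
cat(sprintf("developmental age %.1f-%.1f weeks, chronological age %.0f-%.0f days\n",
            min(cohort$records$developmental_age_weeks),
            max(cohort$records$developmental_age_weeks),
            min(cohort$records$chronological_age_days),
            max(cohort$records$chronological_age_days)))
cat(sprintf("wrote cohort.csv, lanes.tsv (%d lanes), reference_lanes.tsv to %s\n",
            length(unique(cohort$lanes$lane_id)), out_dir))
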