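#!/usr/bin/env Rscript
# Step 2 -- band detection, region calibration and profile classification.
#
# Reads the lane densitometry written by step 1, calibrates the
# acidic/neutral/basic regions from the reference lanes (the neutral zone is
# the exclusion of the two reference supports), detects bands in every
# sample lane, and classifies each lane as foetal, mixed or adult from its
# three most intense bands.

suppressMessages(library(eposwitch))

in_dir <- "results/cohort"
stopifnot(file.exists(file.path(in_dir, "lanes.tsv")))

lanes <- read_lanes(file.path(in_dir, "lanes.tsv"))
refs <- read_lanes(file.path(in_dir, "reference_lanes.tsv"))

regions <- calibrate_regions(
  detect_bands(refs[refs$lane_kind == "acidic_reference", ]),
  detect_bands(refs[refs$lane_kind == "basic_reference", ]))
cat(sprintf("calibrated regions: acidic [0, %.3f], neutral (%.3f, %.3f), basic [%.3f, 1]\n",
            regions$a, regions$a, regions$b, regions$b))

ids <- unique(lanes$lane_id)
bands <- do.call(rbind, lapply(ids, function(id) {
  b <- detect_bands(lanes[lanes$lane_id == id, ])
  assign_regions_and_index(b, regions)
}))
calls <- call_profiles(lanes, regions)

utils::write.table(bands, file.path(in_dir, "bands.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.csv(calls, file.path(in_dir, "calls.csv"), row.names = FALSE)

cat(sprintf("detected %.1f bands per lane on average (range %d-%d)\n",
            nrow(bands) / length(ids),
            min(table(bands$lane_id)), max(table(bands$lane_id))))
cat("profile calls:\n")
print(table(calls$profile_class))
cat(sprintf("wrote bands.tsv and calls.csv to %s\n", in_dir))
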