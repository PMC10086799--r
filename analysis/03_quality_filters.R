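#!/usr/bin/env Rscript
# Step 3: quality filtering and rarefaction, in the fixed order
# shape outlier -> wing-angle differential -> two-stage rarefaction.
#
# Museum specimens with unusual wing shapes (pooled Procrustes distance
# above Q3) or tilted mounting (angle differential above Q3 + IQR) would
# inflate apparent asymmetry; rarefaction then evens out collection
# intensity across species, month, year, region and caste, capping each
# year at 20 specimens.

suppressPackageStartupMessages(library(wingfa))

configs <- read_tps("results/simdata/landmarks.tps")
meta <- read_specimen_metadata("results/simdata/metadata.tsv")
fa <- read.csv("results/fa_table.csv")
angles <- read.csv("results/wing_angles.csv")

meta <- exclude_overwintered_queens(meta)
paired <- pair_wings(configs, meta)
paired_configs <- configs[vapply(configs, function(x)
  x$specimen_id %in% names(paired$pairs), TRUE)]
alignment <- gpa(paired_configs, reflect_side = "left")

step1 <- shape_outlier_filter(alignment)
cat("Shape outlier filter: removed", step1$report$n_removed, "of",
    step1$report$n_in, "(pooled wing distance > Q3 =",
    signif(step1$report$threshold, 3), ")\n")

step2 <- angle_differential_filter(angles[angles$specimen_id %in% step1$kept, ])
cat("Angle differential filter: removed", step2$report$n_removed,
    "(differential >", signif(step2$report$threshold, 3), "deg)\n")

records <- meta[match(step2$kept, meta$specimen_id), ]
reg <- assign_region(records$latitude, records$longitude,
                     read_region_geometry())
records$climate_region <- reg$region

step3 <- rarefy(records, per_year_cap = 20L, seed = 2L)
cat("Rarefaction:", step3$report$n_out[2], "specimens kept",
    "(stage 1 one-per-group:", step3$report$n_out[1], ")\n")

report <- rbind(step1$report, step2$report, step3$report)
write.csv(report[, c("step", "threshold", "n_in", "n_removed", "n_out")],
          "results/filter_report.csv", row.names = FALSE)
write.csv(step3$kept, "results/filtered_records.csv", row.names = FALSE)
cat("Wrote results/filter_report.csv, results/filtered_records.csv\n")
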