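#!/usr/bin/env Rscript
# Step 1: generate the century-scale synthetic collection.
#
# Emits the raw inputs every later step consumes, in the exact dialects
# the ingest functions read: a TPS file of all digitisations (two wings x
# two replicates per specimen), a tab-delimited specimen metadata table
# and an annual regional climate table, plus the generator's ground truth
# for later scoring.

suppressPackageStartupMessages(library(wingfa))

seed <- 1L
out_dir <- "results/simdata"

params <- century_scale_scenario(seed = seed)
sim <- simulate_dataset(params)
write_dataset(sim, out_dir)

cat("Simulated", params$n_specimens, "specimens,",
    length(sim$configs), "digitised wings ->", out_dir, "\n")
cat("Species counts:\n")
print(table(sim$metadata$species))
cat("Years span", min(sim$truth$year), "-", max(sim$truth$year),
    "| mean injected FA magnitude:",
    signif(mean(sim$truth$fa_true), 3), "\n")
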