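#!/usr/bin/env Rscript
# Stage 1: generate the survey-like synthetic inputs.
#
# Emulates the structure of a zone-level analysis of community-based
# health insurance coverage: 83 zones, 6 of them non-sampled, zone sample
# sizes between 15 and 120 households, 8 census-style auxiliary
# covariates, a logit linking model with area-effect variance 0.3243 and
# mean coverage near 28%.  Writes the area table and the generating truth.

suppressPackageStartupMessages(library(zonesae))

seed <- 20260919 %% 100000
cfg <- emdhs_config(seed = seed)
sim <- simulate_areas(cfg)

dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
write_area_table(sim$table, "results/synthetic/area_table.csv")
utils::write.csv(sim$truth, "results/synthetic/truth.csv", row.names = FALSE)

cat(sprintf("simulated %d zones (%d sampled, %d non-sampled)\n",
            nrow(sim$table), sum(sim$table$sampled),
            sum(!sim$table$sampled)))
cat(sprintf("true coverage: mean %.3f, range %.3f-%.3f\n",
            mean(sim$truth$p_true), min(sim$truth$p_true),
            max(sim$truth$p_true)))
cat(sprintf("zone sample sizes: %d-%d households (median %d)\n",
            min(sim$table$n[sim$table$sampled]), max(sim$table$n),
            median(sim$table$n[sim$table$sampled])))
cat("wrote results/synthetic/area_table.csv and truth.csv\n")
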