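#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a 10-participant, 6-week cohort with ground truth: embedded
# temperature sensor traces (10-min sampling, 0.1 degC quantization), daily
# self-report logs with recall noise, phantom wear days and a single
# high-missingness participant. Writes the raw data files every later stage
# consumes.

suppressPackageStartupMessages(library(bracewear))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)
cohort <- simulate_cohort(cfg)

write_sensor_csv(cohort$sensor, file.path(out, "sensor.csv"))
write_selfreport_csv(cohort$selfreport, file.path(out, "selfreport.csv"))
write_truth_json(cohort$truth, file.path(out, "truth.json"))

truth_sum <- summarize_wear(cohort$truth$daily)
n_log <- nrow(cohort$selfreport)
n_expected <- cfg$n_participants * cfg$n_days
cat(sprintf(
  "Cohort: %d participants x %d days -> %d sensor samples\n",
  cfg$n_participants, cfg$n_days, nrow(cohort$sensor)))
cat(sprintf(
  "True wear: avg %.0f min/day (participant range %.0f-%.0f), %d-%d days worn\n",
  mean(truth_sum$avg_daily_minutes),
  min(truth_sum$avg_daily_minutes), max(truth_sum$avg_daily_minutes),
  min(truth_sum$days_worn), max(truth_sum$days_worn)))
cat(sprintf("Self-report: %d of %d entries present (%d missing)\n",
            n_log, n_expected, n_expected - n_log))
cat("Wrote sensor.csv, selfreport.csv, truth.json under", out, "\n")
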