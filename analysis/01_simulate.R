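#!/usr/bin/env Rscript
# Simulate the synthetic study world: a UK-like weather-station network
# (1933-1971) and a 20,000-person cohort whose metabolic outcomes embed a
# known effect of the regional temperature anomaly on the true conception
# day. Writes the station records, the cohort, and the ground truth (the
# latter is test-only and never consumed by the analysis stages).

suppressPackageStartupMessages(library(periclim))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260901L)
world <- simulate_world(cfg)

write_station_table(world$network, "results/data/stations.csv")
write_cohort_table(world$cohort, "results/data/cohort.csv")
truth <- data.table::data.table(
  participant_id = world$truth$participant_id,
  true_doc = world$truth$true_doc,
  true_anomaly = world$truth$true_anomaly
)
data.table::fwrite(truth, "results/data/ground_truth_TEST_ONLY.csv")
data.table::fwrite(
  data.table::data.table(outcome = names(cfg$true_alpha),
                         true_alpha = as.numeric(cfg$true_alpha)),
  "results/data/true_alpha_TEST_ONLY.csv")

cat(sprintf("Simulated %d stations (%d daily records) and %d participants.\n",
            nrow(world$network$stations), nrow(world$network$records),
            nrow(world$cohort)))
cat(sprintf("Conceptions span %s to %s; gestation SD %.0f days.\n",
            min(world$truth$true_doc), max(world$truth$true_doc),
            cfg$gestation_sd))
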