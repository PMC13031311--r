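#!/usr/bin/env Rscript
# Back-of-envelope translations of the fitted coefficients: percent of an
# outcome SD per degC, and the implied effects under a +2 degC (climate
# change) and +6.5 degC (historical indoor-warming) scenario, with BMI
# translated into body-weight grams for a 1.80-m adult.

suppressPackageStartupMessages(library(periclim))

results <- data.table::fread("results/results.csv")
cohort <- read_cohort_table("results/data/cohort.csv")
outcomes <- c("bmi", "wc", "hba1c", "tg", "chol")
sds <- vapply(outcomes, function(o) sd(cohort[[o]], na.rm = TRUE), numeric(1))

main <- results[results$stratum == "all" & results$family == "linear" &
                  results$window == "-5w;+3w", ]
scen <- scenario_table(main, sds, delta_ts = c(2, 6.5))
data.table::fwrite(scen, "results/scenarios.csv")

cat("Widest-window (-5w;+3w) coefficients under warming scenarios:\n")
for (i in seq_len(nrow(scen))) {
  cat(sprintf("  %-6s +%.1f degC: effect %+0.4f units (%.2f %%SD)%s\n",
              scen$outcome[i], scen$delta_t[i], scen$effect[i],
              round_half_up(scen$pct_sd[i], 2),
              ifelse(is.na(scen$weight_g[i]), "",
                     sprintf(" = %+.0f g body weight at 1.80 m", scen$weight_g[i]))))
}
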