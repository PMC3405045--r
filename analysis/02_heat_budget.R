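#!/usr/bin/env Rscript
# Stage 2: convert region surface temperatures into dry heat loss per
# region (radiative + forced convective), per (bird x ambient step).
# Reads the stage-1 outputs; writes the heat-budget table.

library(billheat)

out <- "results/analysis"
cohort <- read.csv(file.path(out, "morphometrics.csv"))
observations <- read.csv(file.path(out, "observations.csv"))

heat <- heat_budget_table(observations, cohort)
write.csv(heat, file.path(out, "heat_budget.csv"), row.names = FALSE)

cat(sprintf("heat budgets for %d (bird x step) means\n", nrow(heat)))
cat(sprintf("percent of total heat lost through the bill: %.1f-%.1f%% (mean %.1f%%)\n",
            min(heat$percent_q_bill), max(heat$percent_q_bill),
            mean(heat$percent_q_bill)))
q_by_ssp <- tapply(heat$q_bill_mw, heat$subspecies, mean)
cat(sprintf("mean bill heat loss: %.2f mW (atlantica) vs %.2f mW (melodia)\n",
            q_by_ssp[["atlantica"]], q_by_ssp[["melodia"]]))
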