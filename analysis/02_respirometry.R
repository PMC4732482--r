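#!/usr/bin/env Rscript
# Stage 2: reduce the raw oxygen traces to per-fish metabolic rates.
#
# Fits a linear regression to every closed-phase O2 trace, converts slopes
# to whole-animal MO2 with background (blank chamber) subtraction, averages
# the three routine windows into RMR, back-extrapolates MMR from the
# logarithmic recovery curve, and records metabolic scope (MMR - RMR) and
# the recovery slope. Writes results/per_fish_summary.csv.
#
# Usage: Rscript analysis/02_respirometry.R

suppressPackageStartupMessages(library(troutherm))

raw <- read_simulated_data("results/simulated")
blank <- estimate_blank_rate(raw$traces)
message(sprintf("background chamber respiration: %.5f mg O2 / l / min", blank))

summaries <- process_respirometry(raw$traces, raw$recovery, raw$fish,
                                  blank_rate = blank)
d <- build_analysis_dataset(raw$fish, summaries)
write.csv(d, "results/per_fish_summary.csv", row.names = FALSE)

agg <- aggregate(cbind(rmr, mmr, scope) ~ acclimation_temp, d, mean)
message("mean whole-animal rates (mg O2/h) by acclimation temperature:")
for (i in seq_len(nrow(agg)))
  message(sprintf("  %2g C: RMR %5.2f  MMR %5.2f  scope %5.2f",
                  agg$acclimation_temp[i], agg$rmr[i], agg$mmr[i], agg$scope[i]))
message(sprintf("%d fish summarised -> results/per_fish_summary.csv", nrow(d)))
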