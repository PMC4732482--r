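#!/usr/bin/env Rscript
# Stage 5: one-call end-to-end reproduction with manifest and report.
#
# Re-runs simulate -> reduce -> analyse through run_pipeline() so a single
# command regenerates every table with the seed and config hash stamped in
# each file, then prints the narrative report. Output in results/run/.
#
# Usage: Rscript analysis/05_report.R [seed]

suppressPackageStartupMessages(library(troutherm))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

run <- run_pipeline(generator_config(), seed = seed, out_dir = "results/run")
writeLines(render_report(run))
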