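#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 79 agents generated from the separable-outcome model (M2Out) with
# heterogeneous weighting factors perform the full online design: 4 blocks
# each of ConflictNoDropout, ConflictMoneyDropout, ConflictShockDropout and
# the three NoConflict counterparts. Explicit probability reports are
# simulated after every NoDropout block. Writes trials, reports and the
# generating parameters under results/.

suppressPackageStartupMessages(library(moralbandit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

dir.create("results", showWarnings = FALSE)
set.seed(seed)

params <- sample_cohort_params(moralbandit:::recovery_hyper(), 79,
                               model = "M2Out", seed = seed)
cohort <- simulate_cohort(params, design_spec("online"), seed = seed + 1L)
reports <- simulate_cohort_reports(cohort, noise_sd = 10, seed = seed + 2L)

write_trials(cohort, "results/trials.csv")
write_true_params(cohort, "results/true_params.csv")
utils::write.csv(as.data.frame(reports), "results/reports.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(stage = "simulate", seed = seed, n_agents = 79L, design = "online",
       generating_model = "M2Out", noise_sd = 10),
  "results/simulate_manifest.json", auto_unbox = TRUE, pretty = TRUE)

lab <- classify_cohort(cohort)
message(sprintf("simulated %d agents, %d trials; preferences: %s",
                79L, nrow(cohort),
                paste(names(table(lab$label)), table(lab$label),
                      sep = "=", collapse = ", ")))
message("wrote results/trials.csv, results/reports.csv, results/true_params.csv")
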