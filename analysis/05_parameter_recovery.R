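#!/usr/bin/env Rscript
# Stage 5: parameter recovery of the weighting factor.
#
# Simulates a fresh cohort of 79 M2Out agents on the 8 ConflictDropout
# blocks, refits the model to the learning trials, and correlates the
# generating with the recovered per-subject weighting factors. This is the
# quantity the acceptance script recomputes.

suppressPackageStartupMessages(library(moralbandit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cohort <- simulate_recovery_cohort(n = 79L, seed = seed)
true_wf <- vapply(attr(cohort, "true_params"), function(p) p$wf, numeric(1))

fit <- suppressWarnings(fit_hierarchical(
  "M2Out", cohort, trials_subset = "learning_only",
  config = fit_config(chains = 4L, warmup = 800L, draws = 500L, thin = 1L,
                      seed = seed)))
est <- point_estimates(fit)

out <- tibble::tibble(subject_id = est$subject_id, true_wf = true_wf,
                      estimated_wf = est$wf)
utils::write.csv(as.data.frame(out), "results/recovery.csv",
                 row.names = FALSE)
r <- cor(out$true_wf, out$estimated_wf)
message(sprintf("r(wf_simulated, wf_estimated) = %.3f over %d agents",
                r, nrow(out)))
message("wrote results/recovery.csv")
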