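#!/usr/bin/env Rscript
# Stage 3: hierarchical Bayesian fits.
#
# Fits M0, M1, M2Out and M2Dec to the first 10 trials of every
# ConflictDropout block (the arbitration design: trial 11 stays held out).
# Posteriors are kept as a runtime artifact for stage 4; point estimates
# and convergence diagnostics are written as CSV.

suppressPackageStartupMessages(library(moralbandit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cohort <- read_trials("results/trials.csv")
models <- c("M0", "M1", "M2Out", "M2Dec")

fits <- lapply(seq_along(models), function(k) {
  message("fitting ", models[k], " ...")
  t0 <- Sys.time()
  fit <- fit_hierarchical(models[k], cohort, trials_subset = "learning_only",
                          config = fit_config(chains = 4L, warmup = 800L,
                                              draws = 500L, thin = 1L,
                                              seed = seed + k))
  message(sprintf("  %s in %.1f s (converged: %s)", models[k],
                  as.numeric(Sys.time() - t0, units = "secs"),
                  fit$diagnostics$converged))
  fit
})
names(fits) <- models
saveRDS(fits, "results/fits.rds") # runtime intermediate for stage 4

est <- dplyr::bind_rows(lapply(models, function(m) {
  tibble::add_column(point_estimates(fits[[m]]), model = m, .before = 1L)
}))
utils::write.csv(as.data.frame(est), "results/point_estimates.csv",
                 row.names = FALSE)

diag <- dplyr::bind_rows(lapply(models, function(m) {
  tibble::add_column(fits[[m]]$diagnostics$table, model = m, .before = 1L)
}))
utils::write.csv(as.data.frame(diag), "results/fit_diagnostics.csv",
                 row.names = FALSE)

message("wrote results/point_estimates.csv, results/fit_diagnostics.csv")
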