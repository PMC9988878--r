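#!/usr/bin/env Rscript
# Stage 4: model comparison.
#
# PSIS-LOO on the fitted learning trials (the three learning models should
# sit within one standard error of each other, far ahead of the chance
# model) and the draw-wise information criterion of the held-out 11th
# trials, where the outcome-weighted model M2Out should separate from the
# field. Also writes the per-subject trial-11 likelihood ratios of M2Out
# against each competitor. Requires stages 1 and 3.

suppressPackageStartupMessages(library(moralbandit))

cohort <- read_trials("results/trials.csv")
fits <- readRDS("results/fits.rds")

cmp <- compare_models(fits, cohort, thin = 2L)
utils::write.csv(as.data.frame(cmp$looic), "results/looic.csv",
                 row.names = FALSE)
utils::write.csv(as.data.frame(cmp$trial11_ic), "results/trial11_ic.csv",
                 row.names = FALSE)

ratios <- dplyr::bind_rows(lapply(c("M1", "M2Dec"), function(m) {
  tibble::add_column(
    subject_likelihood_ratio(fits[["M2Out"]], fits[[m]], cohort),
    comparison = paste0("M2Out_vs_", m), .before = 1L)
}))
utils::write.csv(as.data.frame(ratios), "results/subject_ratios.csv",
                 row.names = FALSE)

message("LOOIC (first 10 trials):")
print(as.data.frame(cmp$looic))
ic <- split(cmp$trial11_ic$ic, cmp$trial11_ic$model)
message("trial-11 IC distribution [min, mean, max] per model:")
print(t(sapply(ic, function(x) round(c(min = min(x), mean = mean(x),
                                       max = max(x)), 1))))
for (m in c("M1", "M2Dec")) {
  won <- mean(ratios$ratio[ratios$comparison == paste0("M2Out_vs_", m)] > 1)
  message(sprintf("M2Out beats %s on the devaluation trial in %.0f%% of subjects",
                  m, 100 * won))
}
message("wrote looic, trial11_ic, subject_ratios under results/")
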