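#!/usr/bin/env Rscript
# Stage 2: descriptive behavioral statistics.
#
# Binomial preference classification (120 conflict learning trials per
# agent), group learning curves, the report-bias statistic per preference
# group, its correlation with choice preference, and the trial-10 vs
# trial-11 devaluation table. Requires results/trials.csv from stage 1.

suppressPackageStartupMessages(library(moralbandit))

cohort <- read_trials("results/trials.csv")
reports <- tibble::as_tibble(utils::read.csv("results/reports.csv"))

labels <- classify_cohort(cohort)
utils::write.csv(as.data.frame(labels), "results/preference_labels.csv",
                 row.names = FALSE)

curves <- learning_curves(cohort, labels)
utils::write.csv(as.data.frame(curves), "results/learning_curves.csv",
                 row.names = FALSE)

conf <- reports[reports$condition == "Conflict", ]
bias <- tapply(report_bias(conf)$bias, conf$subject_id, mean)
bias_tbl <- tibble::tibble(subject_id = as.integer(names(bias)),
                           mean_bias = as.numeric(bias))
bias_tbl <- dplyr::left_join(labels, bias_tbl, by = "subject_id")
utils::write.csv(as.data.frame(bias_tbl), "results/report_bias.csv",
                 row.names = FALSE)

deval <- devaluation_summary(cohort, labels)
utils::write.csv(as.data.frame(deval), "results/devaluation.csv",
                 row.names = FALSE)

r_pref_bias <- preference_bias_correlation(bias_tbl$prop_considerate,
                                           bias_tbl$mean_bias)
by_group <- tapply(bias_tbl$mean_bias, bias_tbl$label, mean)
message(sprintf("preference counts: %s",
                paste(names(table(labels$label)), table(labels$label),
                      sep = "=", collapse = ", ")))
message(sprintf("mean report bias by group: %s",
                paste(names(by_group), round(by_group, 1),
                      sep = "=", collapse = ", ")))
message(sprintf("Pearson r(preference, bias) = %.2f", r_pref_bias))
message("wrote preference_labels, learning_curves, report_bias, devaluation under results/")
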