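#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 100 patients in a manic/mixed episode (baseline YMRS >= 20, randomized 1:1
# to lithium-like vs quetiapine-like arms) and 63 matched healthy controls,
# each with regional gray-matter density samples at baseline, week 1 and
# week 6. The cohort is fully determined by the seed; later stages regenerate
# it from the same seed instead of shipping ~22 million raw sample rows.

library(morphconn)

seed <- 20260901L
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

cl <- cohort$clinical
utils::write.csv(cl, "results/clinical.csv", row.names = FALSE)

base <- cl[cl$timepoint == "baseline", ]
wk6 <- cl[cl$timepoint == "week6", ]
pat <- base$group == "patient"
cat(sprintf("\nBaseline YMRS (patients): mean %.1f, range %d-%d\n",
            mean(base$ymrs[pat]), min(base$ymrs[pat]), max(base$ymrs[pat])))
red <- (base$ymrs[pat] - wk6$ymrs[wk6$group == "patient"]) / base$ymrs[pat]
cat(sprintf("Week-6 YMRS reduction: responders %.0f%%, non-responders %.0f%% (n = %d / %d)\n",
            100 * mean(red[base$responder[pat]]),
            100 * mean(red[!base$responder[pat]]),
            sum(base$responder[pat]), sum(!base$responder[pat])))
cat(sprintf("Arms: %s\n", paste(names(table(base$arm[pat])),
                                table(base$arm[pat]), collapse = ", ")))
cat("\nWrote results/clinical.csv\n")
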