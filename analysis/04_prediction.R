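#!/usr/bin/env Rscript
# Stage 4: predict treatment response from baseline connectomes.
#
# Linear SVM (C = 1) on the 4005 upper-triangle KLS edge features of each
# patient's baseline network, 10-fold stratified cross-validation with
# training-fold-only standardization, permutation significance (99 label
# permutations), and the per-region mean-absolute-weight ranking.

library(morphconn)

seed <- 20260901L
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(seed = seed))
cl <- cohort$clinical
pat_base <- cl[cl$group == "patient" & cl$timepoint == "baseline", ]
pat_wk6 <- cl[cl$group == "patient" & cl$timepoint == "week6", ]

message("building ", nrow(pat_base), " baseline patient networks ...")
networks <- build_cohort_networks(cohort, timepoints = "baseline")
networks <- networks[paste0(pat_base$subject_id, ".baseline")]
x <- connectome_feature_matrix(networks)
labels <- classify_responder(pat_base$ymrs, pat_wk6$ymrs)
cat(sprintf("responders: %d, non-responders: %d\n",
            sum(labels == "responder"), sum(labels == "non-responder")))

report <- cross_validated_classification(x, labels, n_folds = 10,
                                         seed = seed + 21)
cat(sprintf("\nMean balanced accuracy (10-fold): %.3f\n",
            report$mean_balanced_accuracy))
cat("Per-fold:", paste(sprintf("%.2f", report$fold_balanced_accuracies),
                       collapse = " "), "\n")

message("permutation significance (99 label permutations) ...")
ps <- permutation_significance(x, labels, n_perm = 99, n_folds = 10,
                               seed = seed + 22)
report$permutation_p <- ps$p
cat(sprintf("Permutation p = %.4f (null accuracies: mean %.3f, max %.3f)\n",
            ps$p, mean(ps$null_accuracies), max(ps$null_accuracies)))

ranking <- nodal_weight_ranking(report)
cat("\nTop 10 regions by mean incident SVM weight:\n")
print(ranking, digits = 3, row.names = FALSE)

utils::write.csv(ranking, "results/nodal_weights.csv", row.names = FALSE)
jsonlite::write_json(list(
  mean_balanced_accuracy = report$mean_balanced_accuracy,
  fold_balanced_accuracies = report$fold_balanced_accuracies,
  permutation_p = ps$p,
  top_regions = ranking$region), "results/prediction.json",
  auto_unbox = TRUE, digits = NA)
message("wrote results/prediction.json and results/nodal_weights.csv")
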