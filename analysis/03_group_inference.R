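#!/usr/bin/env Rscript
# Stage 3: case-control and longitudinal inference on the metric AUCs
# produced by 02_networks_metrics.R.
#
# - permutation tests (10,000 reallocations) of baseline group differences in
#   the global metric AUCs
# - per-region nodal screening with the 2-of-3 rule at p < 0.05 uncorrected
# - group-by-time mixed models (subject random intercept, age and sex
#   covariates) for Cp and Lp
# - treatment-arm-by-time contrast (expected null: both arms share dynamics)
# - correlations of baseline-to-week-6 metric change with YMRS change, with
#   Benjamini-Hochberg adjustment
# - ICC reliability of control-group AUCs across the three scans

library(morphconn)

seed <- 20260901L
aucs <- utils::read.csv("results/global_auc.csv")
nodal <- utils::read.csv("results/nodal_auc_baseline.csv")
cl <- utils::read.csv("results/clinical.csv")

demo <- cl[!duplicated(cl$subject_id),
           c("subject_id", "group", "arm", "age", "sex")]
aucs <- merge(aucs, demo, by = "subject_id")
base <- aucs[aucs$timepoint == "baseline", ]

## baseline case-control permutation tests -----------------------------------
mets <- c("Cp", "Lp", "Eglob", "Eloc")
perm_tab <- do.call(rbind, lapply(mets, function(m) {
  pr <- permutation_test(base[[m]][base$group == "patient"],
                         base[[m]][base$group == "control"],
                         n_perm = 10000, seed = seed + 11)
  data.frame(metric = m, mean_patient = mean(base[[m]][base$group == "patient"]),
             mean_control = mean(base[[m]][base$group == "control"]),
             observed_diff = pr$observed, p = pr$p_two_tailed)
}))
utils::write.csv(perm_tab, "results/group_auc_tests.csv", row.names = FALSE)
cat("Baseline group differences in metric AUCs (10,000 permutations):\n")
print(perm_tab, digits = 3, row.names = FALSE)

## nodal screening: 2-of-3 rule ----------------------------------------------
nodal$subject_id <- sub("\\.[^.]+$", "", nodal$key)
nodal <- merge(nodal, demo[, c("subject_id", "group")], by = "subject_id")
regions <- unique(nodal$region)
p_tab <- do.call(rbind, lapply(regions, function(rg) {
  d <- nodal[nodal$region == rg, ]
  ps <- vapply(c("degree", "efficiency", "betweenness"), function(m) {
    permutation_test(d[[m]][d$group == "patient"], d[[m]][d$group == "control"],
                     n_perm = 1000, seed = seed + 13)$p_two_tailed
  }, numeric(1))
  data.frame(region = rg, degree = ps[1], efficiency = ps[2],
             betweenness = ps[3])
}))
flags <- abnormal_regions(p_tab)
utils::write.csv(flags, "results/nodal_flags.csv", row.names = FALSE)
cat(sprintf("\nRegions flagged by the 2-of-3 nodal rule: %d of %d\n",
            sum(flags$abnormal), nrow(flags)))
print(flags[flags$abnormal, c("region", "degree", "efficiency", "betweenness")],
      digits = 2, row.names = FALSE)

## longitudinal mixed models ---------------------------------------------------
long_tests <- do.call(rbind, lapply(c("Cp", "Lp"), function(m) {
  lt <- data.frame(value = aucs[[m]], subject_id = aucs$subject_id,
                   timepoint = aucs$timepoint, group = aucs$group,
                   age = aucs$age, sex = aucs$sex)
  grp_time <- interaction_model(lt)
  # arm-by-time within patients: built to be null (both arms share dynamics)
  pat <- lt[aucs$group == "patient", ]
  pat$group <- aucs$arm[aucs$group == "patient"]
  arm_time <- interaction_model(pat)
  data.frame(metric = m,
             effect = c("group:time", "arm:time"),
             F = c(grp_time$F, arm_time$F),
             p = c(grp_time$p, arm_time$p))
}))
long_tests$q <- fdr_adjust(long_tests$p)
utils::write.csv(long_tests, "results/interaction_tests.csv", row.names = FALSE)
cat("\nGroup-by-time and arm-by-time mixed-model tests:\n")
print(long_tests, digits = 3, row.names = FALSE)

## symptom-change correlations -------------------------------------------------
pat_ids <- demo$subject_id[demo$group == "patient"]
d_ymrs <- vapply(pat_ids, function(s) {
  cl$ymrs[cl$subject_id == s & cl$timepoint == "baseline"] -
    cl$ymrs[cl$subject_id == s & cl$timepoint == "week6"]
}, numeric(1))
corr_tab <- do.call(rbind, lapply(c("Cp", "Lp"), function(m) {
  d_met <- vapply(pat_ids, function(s) {
    aucs[[m]][aucs$subject_id == s & aucs$timepoint == "baseline"] -
      aucs[[m]][aucs$subject_id == s & aucs$timepoint == "week6"]
  }, numeric(1))
  cc <- change_correlation(d_met, d_ymrs)
  data.frame(metric = m, r = cc$r, p = cc$p, n = cc$n)
}))
corr_tab$q <- fdr_adjust(corr_tab$p)
utils::write.csv(corr_tab, "results/change_correlations.csv", row.names = FALSE)
cat("\nMetric-change vs YMRS-change correlations (baseline to week 6):\n")
print(corr_tab, digits = 3, row.names = FALSE)

## control-group reliability ---------------------------------------------------
ctl_ids <- demo$subject_id[demo$group == "control"]
icc_tab <- do.call(rbind, lapply(mets, function(m) {
  mat <- t(vapply(ctl_ids, function(s) {
    v <- aucs[aucs$subject_id == s, ]
    v[[m]][order(match(v$timepoint, c("baseline", "week1", "week6")))]
  }, numeric(3)))
  r <- icc(mat)
  data.frame(metric = m, icc = r$icc, category = r$category)
}))
utils::write.csv(icc_tab, "results/icc_controls.csv", row.names = FALSE)
cat("\nControl-group ICC(3,1) across the three scans:\n")
print(icc_tab, digits = 3, row.names = FALSE)
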