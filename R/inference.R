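#' Nonparametric permutation test for a group difference
#'
#' Tests the difference in group means of a network metric (typically an AUC
#' value per subject) by randomly reallocating all values into two groups of
#' the original sizes and recomputing the mean difference. The two-tailed
#' p-value uses the add-one correction
#' `p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`, so it is never exactly
#' zero and is valid under the null.
#'
#' @param a,b Numeric metric values for the two groups (each >= 2 values).
#' @param n_perm Number of label reallocations (default 10000).
#' @param seed Integer seed; the test is deterministic given it.
#' @return Object of class `permutation_result`: list with `observed`
#'   (mean(a) - mean(b)), `null_distribution`, `p_two_tailed`, `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("permutation_test(): both groups need at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("permutation_test(): non-finite metric values", call. = FALSE)
  }
  if (n_perm < 1L) {
    stop("permutation_test(): 'n_perm' must be positive", call. = FALSE)
  }
  observed <- mean(a) - mean(b)
  pool <- c(a, b)
  n_a <- length(a)
  n <- length(pool)
  total <- sum(pool)
  set.seed(seed)
  # mean(a*) - mean(b*) reconstructed from the permuted group-a sum
  null <- vapply(seq_len(n_perm), function(r) {
    s_a <- sum(pool[sample.int(n, n_a)])
    s_a / n_a - (total - s_a) / (n - n_a)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  structure(list(observed = observed, null_distribution = null,
                 p_two_tailed = p, n_perm = as.integer(n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed diff = %.4g, p = %.4g (%d permutations)\n",
              x$observed, x$p_two_tailed, x$n_perm))
  invisible(x)
}

#' Flag regions abnormal in at least two of three nodal centralities
#'
#' A region is called abnormal when at least two of its three nodal
#' centrality p-values (degree, efficiency, betweenness) fall below `alpha`
#' (uncorrected) — the screening rule used for reporting regionally altered
#' nodal topology.
#'
#' @param p_table data.frame or matrix with columns `degree`, `efficiency`,
#'   `betweenness` (p-values) and optionally a `region` column or rownames.
#' @param alpha Per-metric significance level (default 0.05).
#' @return data.frame with the three p-values, `n_significant` and logical
#'   `abnormal` per region.
#' @export
abnormal_regions <- function(p_table, alpha = 0.05) {
  p_table <- as.data.frame(p_table)
  need <- c("degree", "efficiency", "betweenness")
  miss <- setdiff(need, names(p_table))
  if (length(miss) > 0L) {
    stop(sprintf("abnormal_regions(): missing metric column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  p <- as.matrix(p_table[, need])
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("abnormal_regions(): p-values must lie in [0, 1]", call. = FALSE)
  }
  n_sig <- rowSums(p < alpha)
  region <- if ("region" %in% names(p_table)) p_table$region
            else if (!is.null(rownames(p_table))) rownames(p_table)
            else sprintf("region_%03d", seq_len(nrow(p)))
  data.frame(region = region, degree = p[, 1], efficiency = p[, 2],
             betweenness = p[, 3], n_significant = n_sig,
             abnormal = n_sig >= 2L, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group-by-time interaction from a mixed-effects model
#'
#' Fits `value ~ group * timepoint + age + sex + (1 | subject_id)` by REML
#' and returns the F test of the interaction (Satterthwaite denominator
#' degrees of freedom). Used to test whether a metric's trajectory over the
#' scans differs between groups (e.g. patients normalizing while controls
#' stay flat); the same machinery serves treatment-by-time contrasts by
#' passing the arm as `group`.
#'
#' @param long_table data.frame with columns `value`, `group`, `timepoint`,
#'   `subject_id`, `age`, `sex` (one row per subject-timepoint).
#' @param effect Name of the fixed effect to test (default the interaction
#'   `"group:timepoint"`).
#' @return Object of class `longitudinal_result`: list with `effect`, `F`,
#'   `p`, `model` (the fitted lmerMod).
#' @export
interaction_model <- function(long_table, effect = "group:timepoint") {
  need <- c("value", "group", "timepoint", "subject_id", "age", "sex")
  miss <- setdiff(need, names(long_table))
  if (length(miss) > 0L) {
    stop(sprintf("interaction_model(): missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(long_table$group)) < 2L) {
    stop("interaction_model(): both groups must be present", call. = FALSE)
  }
  if (length(unique(long_table$timepoint)) < 2L) {
    stop("interaction_model(): at least two timepoints are required",
         call. = FALSE)
  }
  long_table$group <- factor(long_table$group)
  long_table$timepoint <- factor(long_table$timepoint,
                                 levels = unique(long_table$timepoint))
  long_table$sex <- factor(long_table$sex)
  fit <- lmerTest::lmer(
    value ~ group * timepoint + age + sex + (1 | subject_id),
    data = long_table, REML = TRUE)
  an <- stats::anova(fit)
  if (!effect %in% rownames(an)) {
    stop(sprintf("interaction_model(): effect '%s' not in the model (have: %s)",
                 effect, paste(rownames(an), collapse = ", ")), call. = FALSE)
  }
  structure(list(effect = effect,
                 F = an[effect, "F value"],
                 p = an[effect, "Pr(>F)"],
                 model = fit),
            class = "longitudinal_result")
}

#' @export
print.longitudinal_result <- function(x, ...) {
  cat(sprintf("Mixed-model effect %s: F = %.3f, p = %.4g\n",
              x$effect, x$F, x$p))
  invisible(x)
}

#' Correlation between metric change and symptom change
#'
#' Pearson correlation (with two-sided p) between per-patient change in a
#' network metric and change in a clinical score, e.g. baseline-to-endpoint
#' reduction in clustering coefficient versus YMRS reduction.
#'
#' @param delta_metric,delta_symptom Paired numeric changes (>= 3 patients).
#' @return List with `r`, `p`, `n`.
#' @export
change_correlation <- function(delta_metric, delta_symptom) {
  if (length(delta_metric) != length(delta_symptom)) {
    stop("change_correlation(): inputs must be paired", call. = FALSE)
  }
  ok <- is.finite(delta_metric) & is.finite(delta_symptom)
  x <- delta_metric[ok]; y <- delta_symptom[ok]
  if (length(x) < 3L) {
    stop("change_correlation(): at least 3 complete pairs are required",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("change_correlation(): zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: monotone, each at least the raw p-value.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("fdr_adjust(): p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify treatment response from YMRS scores
#'
#' Responder status is a reduction of at least 50 percent from the baseline
#' YMRS score.
#'
#' @param ymrs_baseline Baseline score(s), must be positive.
#' @param ymrs_endpoint Endpoint score(s).
#' @return Character vector: `"responder"` or `"non-responder"`.
#' @export
classify_responder <- function(ymrs_baseline, ymrs_endpoint) {
  if (any(ymrs_baseline <= 0)) {
    stop("classify_responder(): baseline YMRS must be positive", call. = FALSE)
  }
  reduction <- (ymrs_baseline - ymrs_endpoint) / ymrs_baseline
  ifelse(reduction >= 0.5, "responder", "non-responder")
}

#' Intraclass correlation for repeated metric measurements
#'
#' ICC(3,1): two-way mixed effects, consistency, single measurement
#' (Shrout-Fleiss), computed from the two-way ANOVA mean squares
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`, with the
#' Cicchetti reliability category attached
#' (< 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, >= 0.75 excellent).
#'
#' @param measurements Numeric matrix, subjects in rows, repeated
#'   measurements (e.g. scans) in columns; >= 3 subjects, >= 2 columns.
#' @return Object of class `reliability_result`: list with `icc`, `category`
#'   (or `"undefined"` when the variance decomposition is degenerate), `n`,
#'   `k`.
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 3L || ncol(m) < 2L || any(!is.finite(m))) {
    stop("icc(): need a finite matrix with >= 3 subjects and >= 2 repeated measurements",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ms_subj <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  ms_meas <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - (n - 1) * ms_subj - (k - 1) * ms_meas
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_subj + (k - 1) * ms_err
  if (!is.finite(denom) || denom <= 0) {
    return(structure(list(icc = NA_real_, category = "undefined", n = n, k = k),
                     class = "reliability_result"))
  }
  val <- (ms_subj - ms_err) / denom
  category <- if (val < 0.40) "poor" else if (val < 0.60) "fair"
              else if (val < 0.75) "good" else "excellent"
  structure(list(icc = val, category = category, n = n, k = k),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (%s; %d subjects x %d measurements)\n",
              x$icc, x$category, x$n, x$k))
  invisible(x)
}
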