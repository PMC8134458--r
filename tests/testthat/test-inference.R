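# Permutation inference, the 2-of-3 nodal rule, longitudinal models,
# correlations, FDR, responder classification, ICC.

test_that("permutation_test handles the exact null and extreme effects", {
  x <- rep(c(1, 2, 3), 4)
  pr <- permutation_test(x, x, n_perm = 500, seed = 1)
  expect_equal(pr$observed, 0)
  expect_equal(pr$p_two_tailed, 1)
  set.seed(2)
  a <- rnorm(30)
  b <- rnorm(30) + 5
  pr2 <- permutation_test(a, b, n_perm = 2000, seed = 3)
  expect_lte(pr2$p_two_tailed, 0.001)
  expect_lt(pr2$observed, 0)
  # determinism and the add-one correction
  pr3 <- permutation_test(a, b, n_perm = 2000, seed = 3)
  expect_identical(pr2$null_distribution, pr3$null_distribution)
  expect_gte(pr2$p_two_tailed, 1 / 2001)
  expect_error(permutation_test(1, a), "at least 2")
})

test_that("permutation p-values are valid under the null", {
  set.seed(4)
  p <- vapply(1:200, function(r) {
    permutation_test(rnorm(15), rnorm(15), n_perm = 200,
                     seed = 1000 + r)$p_two_tailed
  }, numeric(1))
  rate <- mean(p <= 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(rate, 0.05 + 3 * se)
  expect_gt(mean(p), 0.4) # roughly uniform, not degenerate
})

test_that("abnormal_regions applies the 2-of-3 rule at 0.05 uncorrected", {
  tab <- data.frame(
    region = c("Frontal_Inf_Oper_R", "Supp_Motor_Area_L", "Insula_R",
               "Parietal_Sup_R", "quiet_region", "one_hit"),
    degree = c(0.010, 0.006, 0.019, 0.117, 0.300, 0.040),
    efficiency = c(0.151, 0.004, 0.045, 0.039, 0.450, 0.200),
    betweenness = c(0.008, 0.341, 0.585, 0.048, 0.900, 0.700))
  out <- abnormal_regions(tab)
  expect_identical(out$abnormal,
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$n_significant, c(2, 2, 2, 2, 0, 1))
  expect_error(abnormal_regions(tab[, -2]), "degree")
  bad <- tab
  bad$degree[1] <- 1.2
  expect_error(abnormal_regions(bad), "0, 1")
})

test_that("interaction_model recovers a built-in group-by-time effect", {
  set.seed(5)
  n <- 40
  subj <- sprintf("s%02d", 1:n)
  grp <- rep(c("patient", "control"), each = n / 2)
  age <- runif(n, 10, 18)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  make_long <- function(slope) {
    do.call(rbind, lapply(1:3, function(tp) {
      data.frame(subject_id = subj, group = grp, age = age, sex = sex,
                 timepoint = c("baseline", "week1", "week6")[tp],
                 value = 0.2 + 0.05 * (grp == "patient") -
                   slope * (grp == "patient") * (tp - 1) +
                   rep(rnorm(n, 0, 0.01), 1) + rnorm(n, 0, 0.005))
    }))
  }
  res <- interaction_model(make_long(0.03))
  expect_identical(res$effect, "group:timepoint")
  expect_lt(res$p, 0.05)
  expect_gte(res$F, 0)
  expect_error(interaction_model(make_long(0)[, -3]), "age")
  one_grp <- make_long(0)
  one_grp$group <- "patient"
  expect_error(interaction_model(one_grp), "both groups")
})

test_that("interaction p-values are well calibrated under the null", {
  set.seed(6)
  p <- vapply(1:30, function(r) {
    n <- 30
    long <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                        timepoint = c("t0", "t1", "t2"))
    long$group <- rep(c("a", "b"), each = n / 2)
    long$age <- rep(runif(n, 10, 18), 3)
    long$sex <- rep(sample(c("M", "F"), n, TRUE), 3)
    long$value <- rep(rnorm(n, 0, 0.02), 3) + rnorm(nrow(long), 0, 0.01)
    interaction_model(long)$p
  }, numeric(1))
  expect_lte(mean(p <= 0.05), 0.2)
  expect_gt(mean(p), 0.3)
})

test_that("change_correlation matches cor.test and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  cc <- change_correlation(x, 2 * x)
  expect_equal(cc$r, 1)
  set.seed(7)
  a <- rnorm(30)
  b <- 0.5 * a + rnorm(30, 0, 0.5)
  cc2 <- change_correlation(a, b)
  ref <- cor.test(a, b)
  expect_equal(cc2$r, unname(ref$estimate))
  expect_equal(cc2$p, ref$p.value)
  expect_error(change_correlation(a, rep(1, 30)), "zero-variance")
  expect_error(change_correlation(1:2, 1:3), "paired")
})

test_that("fdr_adjust equals the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(fdr_adjust(0.3), 0.3)
  expect_identical(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (r in 1:200) {
    p <- runif(sample(1:20, 1))
    q <- fdr_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("classify_responder applies the 50 percent YMRS reduction rule", {
  expect_identical(classify_responder(20, 10), "responder")
  expect_identical(classify_responder(20, 11), "non-responder")
  expect_identical(classify_responder(40, 0), "responder")
  expect_error(classify_responder(0, 0), "positive")
  # scale invariance
  set.seed(9)
  base <- sample(20:40, 50, replace = TRUE)
  end <- sample(0:40, 50, replace = TRUE)
  expect_identical(classify_responder(base, end),
                   classify_responder(3 * base, 3 * end))
})

test_that("icc returns ICC(3,1) with Cicchetti categories", {
  m <- cbind(1:10, 1:10, 1:10)
  r <- icc(m)
  expect_equal(r$icc, 1, tolerance = 1e-9)
  expect_identical(r$category, "excellent")
  # degenerate: no variance anywhere
  expect_identical(icc(matrix(2, 5, 3))$category, "undefined")
  expect_error(icc(m[1:2, ]), "3 subjects")
  # population ICC 0.5 lands in the fair band on a large sample
  set.seed(10)
  subj <- rnorm(600, 0, 1)
  meas <- sapply(1:3, function(k) subj + rnorm(600, 0, 1))
  r2 <- icc(meas)
  expect_equal(r2$icc, 0.5, tolerance = 0.07)
  expect_identical(r2$category, "fair")
  # independent repeats: reliability near zero
  set.seed(11)
  null_icc <- vapply(1:30, function(r) icc(matrix(rnorm(45), 15, 3))$icc,
                     numeric(1))
  expect_lt(abs(mean(null_icc)), 0.12)
})

test_that("icc agrees with the ANOVA mean-square definition", {
  set.seed(12)
  m <- matrix(rnorm(60, 5, 2), 20, 3) + rnorm(20)
  fit <- summary(stats::aov(value ~ subject + rater,
                            data = data.frame(value = as.vector(m),
                                              subject = factor(row(m)),
                                              rater = factor(col(m)))))[[1]]
  msb <- fit["subject", "Mean Sq"]
  mse <- fit["Residuals", "Mean Sq"]
  expect_equal(icc(m)$icc, (msb - mse) / (msb + 2 * mse), tolerance = 1e-10)
})
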