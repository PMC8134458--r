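# Synthetic cohort generator: closed-form KLS oracle, config validation,
# determinism, and the clinical structure the downstream analyses rely on.

test_that("gaussian_kls matches closed form and numerical integration", {
  expect_identical(gaussian_kls(0, 1, 0, 1), 1)
  expect_equal(gaussian_kls(0, 1, 1, 1), exp(-1), tolerance = 1e-12)
  # numerical-integration oracle for the symmetric KL of two Gaussians
  num_kl <- function(m1, s1, m2, s2) {
    f <- function(x) dnorm(x, m1, s1) * (dnorm(x, m1, s1, log = TRUE) -
                                           dnorm(x, m2, s2, log = TRUE))
    g <- function(x) dnorm(x, m2, s2) * (dnorm(x, m2, s2, log = TRUE) -
                                           dnorm(x, m1, s1, log = TRUE))
    integrate(f, -30, 30, rel.tol = 1e-10)$value +
      integrate(g, -30, 30, rel.tol = 1e-10)$value
  }
  cases <- list(c(0, 1, 1, 1), c(0.3, 0.05, 0.35, 0.08), c(-1, 2, 1, 0.5))
  for (cs in cases) {
    expect_equal(gaussian_kls(cs[1], cs[2], cs[3], cs[4]),
                 exp(-num_kl(cs[1], cs[2], cs[3], cs[4])), tolerance = 1e-7)
  }
  # large separation limit
  expect_equal(gaussian_kls(0, 1, 5, 1), exp(-25), tolerance = 1e-12)
  expect_lt(gaussian_kls(0, 1, 5, 1), 1e-10)
  expect_error(gaussian_kls(0, 0, 0, 1), "sigma")
  expect_error(gaussian_kls(0, 1, 0, -1), "sigma")
})

test_that("cohort_config validates fields with named messages", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(n_controls = -3), "n_controls")
  expect_error(cohort_config(n_voxels_per_region = 2.5), "n_voxels_per_region")
  expect_error(cohort_config(arm_split = 1), "arm_split")
  expect_error(cohort_config(responder_fraction = 0), "responder_fraction")
  expect_error(cohort_config(patient_effect = 1.5), "patient_effect")
  expect_error(cohort_config(coupling = -0.1), "coupling")
  expect_error(cohort_config(timepoints = c("a", "a")), "timepoints")
  expect_error(cohort_config(normalization_rate = c(bad = 0.5)),
               "normalization_rate")
  expect_error(cohort_config(signal_region = 120), "signal_region")
})

test_that("generate_cohort reproduces the study group sizes and scan labels", {
  cfg <- cohort_config(n_patients = 100, n_controls = 63,
                       n_voxels_per_region = 40, seed = 1)
  ch <- generate_cohort(cfg)
  base <- ch$clinical[ch$clinical$timepoint == "baseline", ]
  expect_identical(sum(base$group == "patient"), 100L)
  expect_identical(sum(base$group == "control"), 63L)
  expect_identical(sort(unique(ch$clinical$timepoint)),
                   sort(c("baseline", "week1", "week6")))
  expect_length(ch$samples, 163L * 3L)
  expect_identical(dim(ch$samples[[1]]), c(90L, 40L))
  # inclusion criterion: manic-range YMRS at baseline, controls unexposed
  expect_true(all(base$ymrs[base$group == "patient"] >= 20))
  expect_true(all(base$arm[base$group == "control"] == "none"))
  expect_true(all(base$arm[base$group == "patient"] %in%
                    c("lithium-like", "quetiapine-like")))
  expect_true(all(ch$samples[[1]] >= 0 & ch$samples[[1]] <= 1))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_patients = 4, n_controls = 3,
                       n_voxels_per_region = 50, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$samples, b$samples)
  c2 <- generate_cohort(cohort_config(n_patients = 4, n_controls = 3,
                                      n_voxels_per_region = 50, seed = 100))
  expect_false(identical(a$samples, c2$samples))
})

test_that("responders have strictly larger week-6 YMRS percent reduction", {
  cfg <- cohort_config(n_patients = 40, n_controls = 2,
                       n_voxels_per_region = 5, seed = 7)
  ch <- generate_cohort(cfg)
  cl <- ch$clinical[ch$clinical$group == "patient", ]
  base <- cl[cl$timepoint == "baseline", ]
  wk6 <- cl[cl$timepoint == "week6", ]
  stopifnot(identical(base$subject_id, wk6$subject_id))
  reduction <- (base$ymrs - wk6$ymrs) / base$ymrs
  expect_true(all(reduction[base$responder] >= 0.5))
  expect_true(all(reduction[!base$responder] < 0.5))
  expect_gt(mean(reduction[base$responder]), mean(reduction[!base$responder]))
  # generator labels agree with the response rule applied to its own scores
  expect_identical(ifelse(base$responder, "responder", "non-responder"),
                   classify_responder(base$ymrs, wk6$ymrs))
})

test_that("null configuration draws patients and controls from one distribution", {
  cfg <- cohort_config(n_patients = 30, n_controls = 30, patient_effect = 0,
                       responder_signal = 0, n_voxels_per_region = 5,
                       timepoints = "baseline",
                       normalization_rate = numeric(0), seed = 3)
  ch <- generate_cohort(cfg)
  mu <- t(vapply(ch$params, `[[`, numeric(90), "mu"))
  grp <- ch$clinical$group
  # generating means differ only by subject-level jitter (sd 0.002):
  # group means should agree to a few jitter standard errors
  gap <- abs(colMeans(mu[grp == "patient", ]) - colMeans(mu[grp == "control", ]))
  expect_lt(max(gap), 4 * 0.002 / sqrt(15))
  sig <- t(vapply(ch$params, `[[`, numeric(90), "sigma"))
  expect_lt(max(abs(colMeans(sig[grp == "patient", ]) -
                      colMeans(sig[grp == "control", ]))), 0.002)
})

test_that("empirical KLS converges to the Gaussian oracle as samples grow", {
  set.seed(11)
  mu <- c(0.45, 0.47)
  sigma <- c(0.012, 0.012)
  truth <- gaussian_kls(mu[1], sigma[1], mu[2], sigma[2])
  err_at <- function(n_vox) {
    mean(replicate(8, {
      m <- build_similarity_matrix(gaussian_region_samples(mu, sigma, n_vox),
                                   region_labels = c("a", "b"))
      abs(m$values[1, 2] - truth)
    }))
  }
  e_small <- err_at(120)
  e_big <- err_at(3000)
  expect_lt(e_big, e_small)
  expect_lt(e_big, 0.03)
})
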