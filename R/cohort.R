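#' Closed-form KLS between two Gaussian densities
#'
#' Analytic Kullback-Leibler based similarity between two univariate normal
#' distributions: `exp(-(KL(P||Q) + KL(Q||P)))` with
#' `KL(N1||N2) = log(s2/s1) + (s1^2 + (m1 - m2)^2) / (2 s2^2) - 1/2`.
#' This is the exact value that the sample-based estimator
#' ([kls()] on kernel density estimates) converges to when regional density
#' samples are Gaussian, and serves as its oracle throughout the test suite.
#'
#' @param mu1,mu2 Means.
#' @param sigma1,sigma2 Standard deviations; must be positive.
#' @return Similarity in (0, 1]; 1 iff the two distributions coincide.
#'   Vectorized over all four arguments.
#' @export
gaussian_kls <- function(mu1, sigma1, mu2, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) {
    stop("gaussian_kls(): 'sigma1' and 'sigma2' must be positive", call. = FALSE)
  }
  kl12 <- log(sigma2 / sigma1) + (sigma1^2 + (mu1 - mu2)^2) / (2 * sigma2^2) - 0.5
  kl21 <- log(sigma1 / sigma2) + (sigma2^2 + (mu2 - mu1)^2) / (2 * sigma1^2) - 0.5
  exp(-(kl12 + kl21))
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults
#' reproduce the study conditions the pipeline is exercised under: 100
#' patients in a manic or mixed episode (baseline YMRS >= 20) randomized
#' 1:1 to two treatment arms, 63 matched healthy controls, scans at
#' baseline, week 1 and week 6, 90 AAL regions with 500 gray-matter density
#' samples each.
#'
#' Regional densities are truncated Gaussians on `[0, 1]` whose means live in
#' `community_count` latent blocks: tight within-block spacing gives strong
#' KLS edges, wide between-block spacing gives weak ones, and two bridge
#' regions per block sit midway toward the next block (on a ring), supplying
#' the long-range shortcuts that make control networks small-world.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_regions Number of parcellation regions (default 90, AAL).
#' @param n_voxels_per_region Density samples drawn per region and scan.
#' @param timepoints Ordered scan labels; the first is baseline.
#' @param arm_split Fraction of patients assigned to the lithium-like arm.
#' @param community_count Number of latent blocks.
#' @param patient_effect Magnitude in `[0, 1]` of the network regularization
#'   shift applied to patients at baseline: within-block jitter tightens,
#'   regional spreads widen and block centers compress toward each other, so
#'   neighboring-block density overlap rises and the thresholded networks
#'   fill with lattice-like proximity edges in place of effectively random
#'   long-range ones — raising both the clustering coefficient and the
#'   characteristic path length. 0 disables it.
#' @param normalization_rate Named vector, one entry per post-baseline
#'   timepoint, each in `[0, 1]`: the fraction of `patient_effect` removed at
#'   that scan for a patient with full normalization propensity.
#' @param responder_fraction Fraction of patients who respond (>= 50 percent
#'   YMRS reduction by the last timepoint).
#' @param coupling Strength in `[0, 1]` tying each patient's network
#'   normalization propensity to their YMRS percent reduction.
#' @param responder_signal Baseline plant at `signal_region` carrying the
#'   treatment-response signal on that region's incident edges: half the
#'   magnitude is added to responders' regional mean and subtracted from
#'   non-responders', and responders' regional spread is inflated by
#'   `3 * responder_signal`. 0 disables it.
#' @param signal_region Region index carrying the responder signal
#'   (default 30, right insula in AAL order).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          n_controls = 63L,
                          n_regions = 90L,
                          n_voxels_per_region = 500L,
                          timepoints = c("baseline", "week1", "week6"),
                          arm_split = 0.5,
                          community_count = 18L,
                          patient_effect = 0.6,
                          normalization_rate = c(week1 = 0.3, week6 = 0.85),
                          responder_fraction = 0.5,
                          coupling = 0.6,
                          responder_signal = 0.08,
                          signal_region = 30L,
                          seed = 1L) {
  chk_count <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
      stop(sprintf("cohort_config(): '%s' must be a positive integer", name),
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_frac <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
      stop(sprintf("cohort_config(): '%s' must lie in (0, 1)", name),
           call. = FALSE)
    }
    as.numeric(x)
  }
  n_patients <- chk_count(n_patients, "n_patients")
  n_controls <- chk_count(n_controls, "n_controls")
  n_regions <- chk_count(n_regions, "n_regions")
  n_voxels_per_region <- chk_count(n_voxels_per_region, "n_voxels_per_region")
  community_count <- chk_count(community_count, "community_count")
  signal_region <- chk_count(signal_region, "signal_region")
  arm_split <- chk_frac(arm_split, "arm_split")
  responder_fraction <- chk_frac(responder_fraction, "responder_fraction")
  timepoints <- as.character(timepoints)
  if (length(timepoints) < 1L || anyDuplicated(timepoints) > 0L) {
    stop("cohort_config(): 'timepoints' must be distinct ordered labels",
         call. = FALSE)
  }
  if (length(patient_effect) != 1L || !is.finite(patient_effect) ||
      patient_effect < 0 || patient_effect > 1) {
    stop("cohort_config(): 'patient_effect' must lie in [0, 1]", call. = FALSE)
  }
  if (length(coupling) != 1L || !is.finite(coupling) ||
      coupling < 0 || coupling > 1) {
    stop("cohort_config(): 'coupling' must lie in [0, 1]", call. = FALSE)
  }
  if (length(responder_signal) != 1L || !is.finite(responder_signal) ||
      responder_signal < 0) {
    stop("cohort_config(): 'responder_signal' must be nonnegative",
         call. = FALSE)
  }
  followups <- timepoints[-1L]
  if (length(followups) > 0L) {
    if (is.null(names(normalization_rate)) ||
        !setequal(names(normalization_rate), followups) ||
        any(!is.finite(normalization_rate)) ||
        any(normalization_rate < 0 | normalization_rate > 1)) {
      stop(paste0("cohort_config(): 'normalization_rate' must be a vector in ",
                  "[0, 1] named by the post-baseline timepoints (",
                  paste(followups, collapse = ", "), ")"), call. = FALSE)
    }
    normalization_rate <- normalization_rate[followups]
  } else {
    normalization_rate <- numeric(0)
  }
  if (signal_region > n_regions) {
    stop("cohort_config(): 'signal_region' exceeds 'n_regions'", call. = FALSE)
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("cohort_config(): 'seed' must be an integer", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, n_controls = n_controls, n_regions = n_regions,
    n_voxels_per_region = n_voxels_per_region, timepoints = timepoints,
    arm_split = arm_split, community_count = community_count,
    patient_effect = as.numeric(patient_effect),
    normalization_rate = normalization_rate,
    responder_fraction = responder_fraction, coupling = as.numeric(coupling),
    responder_signal = as.numeric(responder_signal),
    signal_region = signal_region, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Patient regularization knobs, as fractions applied at full effect (e = 1):
# 'cohesion' shrinks within-block jitter, 'widen' inflates regional spread,
# 'compress' pulls block centers together. Widening and compression move the
# next- and second-nearest block bands into the similarity estimator's
# resolvable range, so patient edge budgets fill with lattice-like proximity
# edges instead of effectively random long-range ones -- the binarized
# network regularizes (higher Cp, higher Lp).
.reg_effect <- c(cohesion = 0.20, widen = 0.35, compress = 0.25)

# Population layout of the latent block structure: per-region community,
# bridge status, community center, and mean offsets. Drawn once per cohort.
cohort_layout <- function(config) {
  n <- config$n_regions
  k <- config$community_count
  community <- sort(rep_len(seq_len(k), n))
  centers <- seq(0.2, 0.8, length.out = max(k, 2L))[seq_len(k)]
  sizes <- tabulate(community, nbins = k)
  n_bridge <- ifelse(sizes >= 4L, 2L, ifelse(sizes >= 3L, 1L, 0L))
  is_bridge <- logical(n)
  for (c_i in seq_len(k)) {
    idx <- which(community == c_i)
    if (n_bridge[c_i] > 0L) {
      is_bridge[utils::tail(idx, n_bridge[c_i])] <- TRUE
    }
  }
  target <- ifelse(community == k, 1L, community + 1L) # ring of blocks
  list(
    community = community,
    center = centers[community],
    target_center = centers[target],
    is_bridge = is_bridge,
    pop_jitter = stats::rnorm(n, 0, 0.005),
    sigma = stats::runif(n, 0.0108, 0.0132)
  )
}

# Region means for one subject-scan at effective regularization e in [0, 1].
# Block centers are compressed toward 0.5 and core jitter tightens; bridge
# regions sit at the midpoint between their block and the next.
region_means <- function(layout, e, subj_jitter) {
  jit <- layout$pop_jitter + subj_jitter
  sq <- 1 - .reg_effect[["compress"]] * e
  center <- 0.5 + (layout$center - 0.5) * sq
  target <- 0.5 + (layout$target_center - 0.5) * sq
  mid <- (center + target) / 2
  mu <- center + jit * (1 - .reg_effect[["cohesion"]] * e)
  bridge_mu <- mid + jit
  mu[layout$is_bridge] <- bridge_mu[layout$is_bridge]
  mu
}

#' Generate a synthetic clinical cohort with community-structured connectomes
#'
#' Draws a full synthetic study: per-subject, per-timepoint regional
#' gray-matter density samples (truncated Gaussians on `[0, 1]` with latent
#' community structure, see [cohort_config()]) plus a clinical table with
#' YMRS/CDRS-R trajectories, demographics, arm assignment and responder
#' status. Patients at baseline are shifted toward network regularization
#' (higher clustering and path length); at follow-up scans the shift decays
#' at `normalization_rate`, scaled per patient by a normalization propensity
#' that is correlated (strength `coupling`) with the patient's YMRS percent
#' reduction. Responder status is assigned first and YMRS trajectories are
#' conditioned on it, so both classes always exist.
#'
#' @param config A [cohort_config()].
#' @return An object of class `morph_cohort`: a list with
#'   \describe{
#'     \item{clinical}{data.frame, one row per subject-timepoint:
#'       `subject_id`, `group`, `arm`, `timepoint`, `age`, `sex`, `ymrs`,
#'       `cdrs`, `responder`.}
#'     \item{samples}{named list (key `"<subject_id>.<timepoint>"`) of
#'       `n_regions x n_voxels_per_region` matrices of density samples.}
#'     \item{params}{same keys: list with the generating `mu` and `sigma`
#'       per region (before truncation), for oracle comparisons.}
#'     \item{layout, config}{the latent layout and the config used.}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("generate_cohort(): 'config' must be built by cohort_config()",
         call. = FALSE)
  }
  set.seed(config$seed)
  layout <- cohort_layout(config)
  n_pat <- config$n_patients
  n_ctl <- config$n_controls
  n_all <- n_pat + n_ctl
  ids <- sprintf("S%03d", seq_len(n_all))
  group <- rep(c("patient", "control"), c(n_pat, n_ctl))

  n_lith <- round(n_pat * config$arm_split)
  arm <- c(sample(rep(c("lithium-like", "quetiapine-like"),
                      c(n_lith, n_pat - n_lith))),
           rep("none", n_ctl))
  age <- round(stats::runif(n_all, 10, 17.9), 1)
  sex <- sample(c("M", "F"), n_all, replace = TRUE, prob = c(0.4, 0.6))

  n_resp <- max(1L, min(n_pat - 1L, round(n_pat * config$responder_fraction)))
  responder <- c(sample(rep(c(TRUE, FALSE), c(n_resp, n_pat - n_resp))),
                 rep(NA, n_ctl))

  tps <- config$timepoints
  n_tp <- length(tps)
  # Fractional YMRS reduction at each follow-up; last-scan reduction defines
  # response (>= 50%) and is drawn conditional on the assigned label.
  u_final <- ifelse(responder[seq_len(n_pat)],
                    0.5 + 0.45 * stats::rbeta(n_pat, 2, 2),
                    0.45 * stats::rbeta(n_pat, 2, 2))
  u <- matrix(0, n_pat, n_tp, dimnames = list(NULL, tps))
  if (n_tp > 1L) {
    u[, n_tp] <- u_final
    if (n_tp > 2L) {
      for (j in 2:(n_tp - 1L)) {
        frac <- (j - 1) / (n_tp - 1)
        u[, j] <- u_final * frac * stats::runif(n_pat, 0.6, 1.4)
      }
      u[, 2:(n_tp - 1L)] <- pmin(u[, 2:(n_tp - 1L), drop = FALSE], 0.95)
    }
  }
  # Normalization propensity: coupled to symptom change, remainder noise.
  norm_prop <- pmin(1, pmax(0, config$coupling * u_final +
                              (1 - config$coupling) * stats::runif(n_pat)))

  ymrs_base <- 20L + stats::rpois(n_pat, 8)
  cdrs_base <- 35L + stats::rpois(n_pat, 8)
  ymrs <- matrix(0L, n_pat, n_tp)
  cdrs <- matrix(0L, n_pat, n_tp)
  ymrs[, 1] <- ymrs_base
  cdrs[, 1] <- cdrs_base
  if (n_tp > 1L) {
    for (j in 2:n_tp) {
      raw <- ymrs_base * (1 - u[, j])
      # floor for responders / ceiling otherwise so that integer rounding
      # never crosses the 50% response boundary at the final scan
      ymrs[, j] <- as.integer(ifelse(responder[seq_len(n_pat)],
                                     floor(raw), ceiling(raw)))
      cdrs[, j] <- as.integer(round(cdrs_base * (1 - 0.6 * u[, j])))
    }
  }

  subj_jitter <- matrix(stats::rnorm(n_all * config$n_regions, 0, 0.002),
                        n_all, config$n_regions)
  sigma_mult <- exp(stats::rnorm(n_all, 0, 0.03))

  clinical <- vector("list", n_all * n_tp)
  samples <- vector("list", n_all * n_tp)
  params <- vector("list", n_all * n_tp)
  keys <- character(n_all * n_tp)
  rate <- c(baseline = 0, config$normalization_rate)
  names(rate)[1] <- tps[1]
  row <- 0L
  for (i in seq_len(n_all)) {
    pat <- group[i] == "patient"
    pat_idx <- if (pat) i else NA_integer_
    for (j in seq_len(n_tp)) {
      row <- row + 1L
      tp <- tps[j]
      e <- 0
      if (pat) {
        e <- config$patient_effect * (1 - rate[[tp]] * norm_prop[pat_idx])
      }
      mu <- region_means(layout, e, subj_jitter[i, ])
      sigma <- layout$sigma * sigma_mult[i] * (1 + .reg_effect[["widen"]] * e)
      if (pat && j == 1L && config$responder_signal > 0) {
        # baseline-only plant at the signal region: responders shift up and
        # broaden, non-responders shift down, so its incident edges carry the
        # predictive signal
        shift <- ifelse(responder[pat_idx], 0.5, -0.5) * config$responder_signal
        mu[config$signal_region] <- mu[config$signal_region] + shift
        if (responder[pat_idx]) {
          sigma[config$signal_region] <-
            sigma[config$signal_region] * (1 + 3 * config$responder_signal)
        }
      }
      x <- matrix(stats::rnorm(config$n_regions * config$n_voxels_per_region,
                               mean = mu, sd = sigma),
                  nrow = config$n_regions)
      x <- pmin(pmax(x, 0), 1)
      key <- paste0(ids[i], ".", tp)
      keys[row] <- key
      samples[[row]] <- x
      params[[row]] <- list(mu = mu, sigma = sigma)
      clinical[[row]] <- data.frame(
        subject_id = ids[i], group = group[i], arm = arm[i], timepoint = tp,
        age = age[i], sex = sex[i],
        ymrs = if (pat) ymrs[pat_idx, j] else stats::rpois(1, 1),
        cdrs = if (pat) cdrs[pat_idx, j] else 17L + stats::rpois(1, 2),
        responder = responder[i],
        stringsAsFactors = FALSE)
    }
  }
  names(samples) <- keys
  names(params) <- keys
  structure(list(
    clinical = do.call(rbind, clinical),
    samples = samples,
    params = params,
    layout = layout,
    config = config
  ), class = "morph_cohort")
}

#' @export
print.morph_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic morphometry cohort: %d patients + %d controls, %d regions, %d scans (%s)\n",
    cfg$n_patients, cfg$n_controls, cfg$n_regions,
    length(cfg$timepoints), paste(cfg$timepoints, collapse = ", ")))
  invisible(x)
}

#' Extract one subject-timepoint profile from a cohort
#'
#' @param cohort A `morph_cohort`.
#' @param subject_id Subject identifier.
#' @param timepoint Scan label; defaults to the cohort's first timepoint.
#' @return A list with the clinical fields of the row plus `region_samples`,
#'   the `n_regions x n_voxels` sample matrix.
#' @export
subject_profile <- function(cohort, subject_id,
                            timepoint = cohort$config$timepoints[1]) {
  key <- paste0(subject_id, ".", timepoint)
  if (!key %in% names(cohort$samples)) {
    stop(sprintf("subject_profile(): no scan '%s' for subject '%s'",
                 timepoint, subject_id), call. = FALSE)
  }
  cl <- cohort$clinical
  rowi <- which(cl$subject_id == subject_id & cl$timepoint == timepoint)
  out <- as.list(cl[rowi, , drop = FALSE])
  out$region_samples <- cohort$samples[[key]]
  out
}
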