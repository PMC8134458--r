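#' Discrete density estimate on a shared grid
#'
#' Gaussian-kernel density estimate of a sample, evaluated on a fixed grid,
#' floored at `eps` and renormalized to unit mass. All KLS computations in the
#' package operate on these discrete estimates, so two regions are always
#' compared on the same support.
#'
#' @param samples Numeric vector of at least `min_samples` finite values.
#' @param grid Strictly increasing support points. If `NULL`, a 256-point grid
#'   spanning `range(samples)` extended by 3 bandwidths is used.
#' @param bw Kernel bandwidth; default Silverman's rule ([stats::bw.nrd0()]).
#' @param eps Floor applied to the mass before renormalization; KL divergence
#'   is undefined at zeros.
#' @param min_samples Minimum sample count accepted.
#' @param label Optional region label used in error messages.
#' @return Object of class `density_estimate`: list with `grid` and `mass`
#'   (nonnegative, summing to 1).
#' @export
estimate_density <- function(samples, grid = NULL, bw = NULL, eps = 1e-10,
                             min_samples = 30L, label = "input") {
  samples <- as.numeric(samples)
  if (length(samples) < min_samples) {
    stop(sprintf(
      "estimate_density(): %s has %d samples; at least %d are required",
      label, length(samples), min_samples), call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop(sprintf("estimate_density(): %s contains non-finite values", label),
         call. = FALSE)
  }
  if (stats::sd(samples) == 0) {
    stop(sprintf(
      "estimate_density(): %s is degenerate (zero variance); KDE undefined",
      label), call. = FALSE)
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(samples)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * bw, max(samples) + 3 * bw,
                length.out = 256L)
  }
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("estimate_density(): 'grid' must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  # stats::density requires an equispaced grid; fall back to direct kernel
  # summation when the caller supplies a non-uniform one
  step <- diff(grid)
  if (max(step) - min(step) < 1e-9 * mean(step)) {
    d <- stats::density(samples, bw = bw, from = grid[1],
                        to = grid[length(grid)], n = length(grid))
    f <- d$y
  } else {
    f <- vapply(grid, function(g) {
      mean(stats::dnorm((g - samples) / bw)) / bw
    }, numeric(1))
  }
  mass <- pmax(f, eps)
  new_density_estimate(grid, mass / sum(mass))
}

new_density_estimate <- function(grid, mass) {
  stopifnot(length(grid) == length(mass), all(mass >= 0),
            abs(sum(mass) - 1) <= 1e-9, all(diff(grid) > 0))
  structure(list(grid = grid, mass = mass), class = "density_estimate")
}

#' Mean of a discrete density estimate
#' @param p A `density_estimate`.
#' @return `sum(grid * mass)`.
#' @export
density_mean <- function(p) sum(p$grid * p$mass)

#' Kullback-Leibler based similarity between two density estimates
#'
#' `exp(-(KL(p||q) + KL(q||p)))`, with each divergence computed by discrete
#' summation over the shared grid. Ranges over (0, 1]; equals 1 exactly when
#' the two estimates coincide, and is symmetric in its arguments.
#'
#' @param p,q `density_estimate` objects on the same grid.
#' @return Similarity in (0, 1].
#' @export
kls <- function(p, q) {
  if (!inherits(p, "density_estimate") || !inherits(q, "density_estimate")) {
    stop("kls(): arguments must be density_estimate objects", call. = FALSE)
  }
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-12 * max(1, max(abs(p$grid)))) {
    stop("kls(): density estimates must share the same grid", call. = FALSE)
  }
  lp <- log(p$mass)
  lq <- log(q$mass)
  exp(-(sum(p$mass * (lp - lq)) + sum(q$mass * (lq - lp))))
}

#' Build a subject's KLS morphological similarity matrix
#'
#' Estimates each region's gray-matter density distribution by Gaussian KDE
#' on a single shared grid (spanning the pooled sample range of all regions,
#' extended by 3 pooled-sample bandwidths) and computes the KLS between all
#' unordered region pairs. The diagonal is set to 1 by convention but is never
#' treated as an edge downstream.
#'
#' @param x Either a subject profile (a list with `region_samples`) or a
#'   numeric matrix with one row per region.
#' @param region_labels Node labels; defaults to [aal90_labels()].
#' @param subject_id Optional identifier attached to the result.
#' @param n_grid Number of shared grid points.
#' @param min_samples Minimum samples per region.
#' @return Object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix, off-diagonal in (0, 1], unit diagonal),
#'   `region_labels`, and `subject_id`.
#' @export
build_similarity_matrix <- function(x, region_labels = NULL,
                                    subject_id = NULL, n_grid = 256L,
                                    min_samples = 30L) {
  if (is.list(x) && !is.null(x$region_samples)) {
    if (is.null(subject_id) && !is.null(x$subject_id)) {
      subject_id <- x$subject_id[1]
    }
    x <- x$region_samples
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("build_similarity_matrix(): 'x' must be a numeric matrix of regional samples",
         call. = FALSE)
  }
  n_regions <- nrow(x)
  if (is.null(region_labels)) region_labels <- aal90_labels(n_regions)
  if (length(region_labels) != n_regions) {
    stop("build_similarity_matrix(): 'region_labels' length must match region count",
         call. = FALSE)
  }
  missing <- which(apply(x, 1L, function(r) any(!is.finite(r))))
  if (length(missing) > 0L) {
    stop(sprintf(
      "build_similarity_matrix(): regions with missing/non-finite samples: %s",
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (ncol(x) < min_samples) {
    stop(sprintf(
      "build_similarity_matrix(): %d samples per region; at least %d are required",
      ncol(x), min_samples), call. = FALSE)
  }
  degenerate <- which(apply(x, 1L, stats::sd) == 0)
  if (length(degenerate) > 0L) {
    stop(sprintf(
      "build_similarity_matrix(): degenerate (zero-variance) region(s): %s",
      paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  pooled <- as.vector(x)
  bw_pool <- stats::bw.nrd0(pooled)
  grid <- seq(min(pooled) - 3 * bw_pool, max(pooled) + 3 * bw_pool,
              length.out = n_grid)
  eps <- 1e-10
  mass <- matrix(0, n_regions, n_grid)
  for (r in seq_len(n_regions)) {
    # same estimator as estimate_density(), without re-validating the shared
    # grid for every region
    f <- stats::density(x[r, ], bw = stats::bw.nrd0(x[r, ]), from = grid[1],
                        to = grid[n_grid], n = n_grid)$y
    f <- pmax(f, eps)
    mass[r, ] <- f / sum(f)
  }
  lmass <- log(mass)
  self_ent <- rowSums(mass * lmass)
  cross <- mass %*% t(lmass)       # cross[i, j] = sum_k p_i log p_j
  kl <- self_ent - cross           # kl[i, j] = KL(p_i || p_j)
  values <- exp(-(kl + t(kl)))
  values <- (values + t(values)) / 2  # enforce exact symmetry
  diag(values) <- 1
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, region_labels = region_labels,
                 subject_id = subject_id),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("KLS similarity matrix%s: %d x %d, off-diagonal range [%.4f, %.4f]\n",
              if (is.null(x$subject_id)) "" else paste0(" (", x$subject_id, ")"),
              n, n, min(off), max(off)))
  invisible(x)
}

# Accept either a similarity_matrix or a plain symmetric numeric matrix.
as_sim_values <- function(m) {
  if (inherits(m, "similarity_matrix")) return(m$values)
  if (is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)) return(m)
  stop("expected a similarity_matrix or a square numeric matrix", call. = FALSE)
}

#' Build similarity matrices for every scan in a cohort
#'
#' @param cohort A `morph_cohort` from [generate_cohort()].
#' @param timepoints Scans to process (default: all in the cohort).
#' @return Named list (key `"<subject_id>.<timepoint>"`) of
#'   `similarity_matrix` objects.
#' @export
build_cohort_networks <- function(cohort,
                                  timepoints = cohort$config$timepoints) {
  keys <- names(cohort$samples)
  tp_of <- sub("^[^.]+\\.", "", keys)
  keys <- keys[tp_of %in% timepoints]
  labels <- aal90_labels(cohort$config$n_regions)
  out <- lapply(keys, function(k) {
    build_similarity_matrix(cohort$samples[[k]], region_labels = labels,
                            subject_id = k)
  })
  names(out) <- keys
  out
}
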