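#' Vectorize a connectome matrix into edge features
#'
#' Flattens the upper triangle (diagonal excluded) of a symmetric matrix in
#' row-major order — for 3 regions the features are the pairs (1,2), (1,3),
#' (2,3) — and records the feature-to-region-pair index map.
#'
#' @param matrix A `similarity_matrix` or square symmetric numeric matrix.
#' @param tol Symmetry tolerance.
#' @return Object of class `feature_vector`: list with `values`
#'   (length N(N-1)/2), `index_map` (two-column matrix of region indices) and
#'   `region_labels`.
#' @export
vectorize_connectome <- function(matrix, tol = 1e-9) {
  labels <- if (inherits(matrix, "similarity_matrix")) matrix$region_labels
            else rownames(matrix)
  m <- as_sim_values(matrix)
  if (max(abs(m - t(m))) > tol) {
    stop("vectorize_connectome(): input matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(m)
  index_map <- t(utils::combn(n, 2L)) # row-major upper triangle
  structure(list(values = m[index_map],
                 index_map = index_map,
                 region_labels = labels),
            class = "feature_vector")
}

#' Reconstruct a symmetric matrix from an edge feature vector
#'
#' Inverse of [vectorize_connectome()]; the diagonal is set to `diag_value`.
#'
#' @param fv A `feature_vector`.
#' @param diag_value Diagonal fill (default 1).
#' @return Symmetric numeric matrix.
#' @export
reconstruct_connectome <- function(fv, diag_value = 1) {
  n <- max(fv$index_map)
  m <- matrix(0, n, n)
  m[fv$index_map] <- fv$values
  m <- m + t(m)
  diag(m) <- diag_value
  if (!is.null(fv$region_labels)) dimnames(m) <- list(fv$region_labels,
                                                      fv$region_labels)
  m
}

#' Stack per-subject connectomes into a feature matrix
#'
#' @param networks Named list of `similarity_matrix` objects (one per subject,
#'   typically baseline scans).
#' @return Numeric matrix, subjects in rows and edge features in columns, with
#'   attributes `index_map` and `region_labels`.
#' @export
connectome_feature_matrix <- function(networks) {
  fvs <- lapply(networks, vectorize_connectome)
  x <- do.call(rbind, lapply(fvs, `[[`, "values"))
  rownames(x) <- names(networks)
  attr(x, "index_map") <- fvs[[1]]$index_map
  attr(x, "region_labels") <- fvs[[1]]$region_labels
  x
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so fold class counts differ by at most one.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(levels(truth), function(cls) {
    in_cls <- truth == cls
    if (!any(in_cls)) return(NA_real_)
    mean(pred[in_cls] == cls)
  }, numeric(1)), na.rm = TRUE)
}

#' Cross-validated linear SVM classification of treatment response
#'
#' Trains a linear support vector machine on baseline connectome edge
#' features under stratified k-fold cross-validation. Features are
#' standardized using training-fold statistics only, so no test information
#' leaks into the model. Performance is summarized as the mean across folds
#' of the balanced accuracy (mean of per-class recalls); the feature weight
#' map is the mean absolute SVM weight across folds, from which per-region
#' (nodal) weights are derived as the mean over each region's incident edges.
#'
#' @param features Subjects x features numeric matrix, e.g. from
#'   [connectome_feature_matrix()] (attributes `index_map`/`region_labels`
#'   are used for the nodal weight map when present).
#' @param labels Two-class labels (responder flags), one per subject.
#' @param n_folds Number of stratified folds (default 10).
#' @param cost SVM regularization constant (default 1).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `classification_report`: list with
#'   `fold_balanced_accuracies`, `mean_balanced_accuracy`, `edge_weights`,
#'   `nodal_weights`, `top_regions`, `fold_class_counts`, `permutation_p`
#'   (NA until [permutation_significance()] is run), `levels`, `n_folds`,
#'   `seed`.
#' @export
cross_validated_classification <- function(features, labels, n_folds = 10L,
                                           cost = 1, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(labels)
  if (nrow(x) != length(y)) {
    stop("cross_validated_classification(): one label per subject required",
         call. = FALSE)
  }
  if (nlevels(y) != 2L) {
    stop("cross_validated_classification(): exactly two classes required",
         call. = FALSE)
  }
  if (min(table(y)) < n_folds) {
    stop(sprintf(
      "cross_validated_classification(): smallest class (%d) is below the fold count (%d)",
      min(table(y)), n_folds), call. = FALSE)
  }
  fold <- stratified_folds(y, n_folds, seed)
  accs <- numeric(n_folds)
  w_abs <- matrix(0, n_folds, ncol(x))
  counts <- matrix(0L, n_folds, 2L, dimnames = list(NULL, levels(y)))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    xtr0 <- x[tr, , drop = FALSE]
    mu <- colMeans(xtr0)
    sd_ <- sqrt(pmax(colSums(xtr0^2) - nrow(xtr0) * mu^2, 0) / (nrow(xtr0) - 1))
    sd_[sd_ == 0] <- 1
    xtr <- sweep(sweep(xtr0, 2L, mu), 2L, sd_, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, mu), 2L, sd_, "/")
    fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, xte)
    accs[f] <- balanced_accuracy(y[!tr], pred)
    w_abs[f, ] <- abs(crossprod(fit$coefs, fit$SV))
    counts[f, ] <- table(y[!tr])
  }
  edge_weights <- colMeans(w_abs)
  index_map <- attr(features, "index_map")
  region_labels <- attr(features, "region_labels")
  nodal <- NULL
  if (!is.null(index_map)) {
    n_regions <- max(index_map)
    nodal <- vapply(seq_len(n_regions), function(r) {
      mean(edge_weights[index_map[, 1] == r | index_map[, 2] == r])
    }, numeric(1))
    if (!is.null(region_labels)) names(nodal) <- region_labels
  }
  report <- structure(list(
    fold_balanced_accuracies = accs,
    mean_balanced_accuracy = mean(accs),
    edge_weights = edge_weights,
    index_map = index_map,
    region_labels = region_labels,
    nodal_weights = nodal,
    fold_class_counts = counts,
    permutation_p = NA_real_,
    levels = levels(y),
    n_folds = as.integer(n_folds),
    seed = as.integer(seed)
  ), class = "classification_report")
  report$top_regions <- if (!is.null(nodal)) {
    nodal_weight_ranking(report)$region
  }
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%d-fold linear SVM: mean balanced accuracy = %.3f",
              x$n_folds, x$mean_balanced_accuracy))
  if (!is.na(x$permutation_p)) cat(sprintf(", permutation p = %.4g", x$permutation_p))
  cat("\n")
  invisible(x)
}

#' Permutation significance of the classification accuracy
#'
#' Re-runs the full cross-validation with randomly permuted labels and
#' returns `p = (1 + #{permuted accuracy >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams cross_validated_classification
#' @param n_perm Number of label permutations (must be positive).
#' @return List with `p`, `observed`, `null_accuracies`.
#' @export
permutation_significance <- function(features, labels, n_perm = 1000L,
                                     n_folds = 10L, cost = 1, seed = 1L) {
  if (length(n_perm) != 1L || n_perm < 1L) {
    stop("permutation_significance(): 'n_perm' must be positive", call. = FALSE)
  }
  observed <- cross_validated_classification(features, labels,
                                             n_folds = n_folds, cost = cost,
                                             seed = seed)$mean_balanced_accuracy
  null_acc <- vapply(seq_len(n_perm), function(r) {
    set.seed(seed + r)
    perm <- sample(labels)
    cross_validated_classification(features, perm, n_folds = n_folds,
                                   cost = cost,
                                   seed = seed + r)$mean_balanced_accuracy
  }, numeric(1))
  list(p = (1 + sum(null_acc >= observed)) / (1 + n_perm),
       observed = observed, null_accuracies = null_acc)
}

#' Rank regions by their mean incident edge weight
#'
#' For each region, the nodal weight is the mean of the (cross-fold mean
#' absolute) SVM weights of its incident edges to the remaining N-1 regions.
#' Regions are ranked in descending nodal weight; ties are broken by
#' ascending region index for determinism.
#'
#' @param report A `classification_report` with edge weights.
#' @param top_n Number of top regions to return (default 10).
#' @return data.frame with `rank`, `region_index`, `region`, `weight`.
#' @export
nodal_weight_ranking <- function(report, top_n = 10L) {
  if (is.null(report$nodal_weights) || length(report$nodal_weights) == 0L) {
    stop("nodal_weight_ranking(): report has no nodal weights", call. = FALSE)
  }
  w <- report$nodal_weights
  idx <- seq_along(w)
  ord <- order(-w, idx)
  top <- utils::head(ord, top_n)
  labels <- if (!is.null(names(w))) names(w) else sprintf("region_%03d", idx)
  data.frame(rank = seq_along(top), region_index = top,
             region = labels[top], weight = unname(w[top]),
             row.names = NULL, stringsAsFactors = FALSE)
}
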