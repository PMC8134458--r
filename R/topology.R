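#' Sparsity threshold scheme
#'
#' The sequence of sparsity values at which similarity matrices are binarized,
#' and over which metric curves are integrated. The default covers 0.10 to
#' 0.34 inclusive in steps of 0.01 (25 thresholds), the regime in which
#' community-structured morphological networks remain estimable for the
#' small-world index.
#'
#' @param s_min,s_max Inclusive endpoints, each in (0, 1).
#' @param step Threshold spacing.
#' @return Object of class `threshold_scheme` with element `s_values`.
#' @export
threshold_scheme <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (s_max < s_min || step <= 0) {
    stop("threshold_scheme(): sparsities must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  s <- seq(s_min, s_max, by = step)
  if (length(s) < 1L || any(s <= 0) || any(s >= 1) || any(diff(s) <= 0)) {
    stop("threshold_scheme(): sparsities must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  structure(list(s_values = s), class = "threshold_scheme")
}

# Upper-triangle edge ordering of a similarity matrix: descending weight,
# ties by ascending (row, column). Sorted once, reused across thresholds.
edge_order <- function(values) {
  n <- nrow(values)
  ut <- which(upper.tri(values))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  w <- values[ut]
  ord <- order(-w, i, j)
  list(i = i[ord], j = j[ord], w = w[ord], n = n)
}

edge_count_at <- function(s, n) {
  m <- n * (n - 1) / 2
  k <- floor(s * m + 0.5) # round half up
  as.integer(k)
}

new_binary_graph <- function(adjacency) {
  n <- nrow(adjacency)
  k <- sum(adjacency) / 2
  structure(list(adjacency = adjacency, n_nodes = n, n_edges = as.integer(k),
                 sparsity = k / (n * (n - 1) / 2)),
            class = "binary_graph")
}

graph_from_edges <- function(eo, k) {
  a <- matrix(0L, eo$n, eo$n)
  if (k > 0L) {
    take <- seq_len(min(k, length(eo$i)))
    a[cbind(eo$i[take], eo$j[take])] <- 1L
    a[cbind(eo$j[take], eo$i[take])] <- 1L
  }
  new_binary_graph(a)
}

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Retains the `round-half-up(s * N(N-1)/2)` strongest off-diagonal edges
#' (ties broken by descending weight, then ascending row and column index)
#' and discards the weights. The diagonal never participates.
#'
#' @param matrix A `similarity_matrix` or square symmetric numeric matrix.
#' @param s Target sparsity in (0, 1): the fraction of all possible edges kept.
#' @return Object of class `binary_graph`: symmetric 0/1 `adjacency` with zero
#'   diagonal, plus `n_edges` and the realized `sparsity`.
#' @export
threshold_by_sparsity <- function(matrix, s) {
  if (length(s) != 1L || !is.finite(s) || s <= 0 || s >= 1) {
    stop("threshold_by_sparsity(): 's' must lie in (0, 1)", call. = FALSE)
  }
  values <- as_sim_values(matrix)
  eo <- edge_order(values)
  graph_from_edges(eo, edge_count_at(s, eo$n))
}

#' Binarize a similarity matrix at every threshold of a scheme
#'
#' @param matrix A `similarity_matrix` or square numeric matrix.
#' @param scheme A [threshold_scheme()].
#' @return List of `binary_graph`, one per sparsity value.
#' @export
threshold_all <- function(matrix, scheme = threshold_scheme()) {
  values <- as_sim_values(matrix)
  eo <- edge_order(values)
  lapply(scheme$s_values, function(s) graph_from_edges(eo, edge_count_at(s, eo$n)))
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficient of a binary graph
#'
#' Mean over all nodes of `2 t_i / (k_i (k_i - 1))`, where `t_i` counts edges
#' among node i's neighbors; nodes of degree < 2 contribute 0.
#'
#' @param graph A `binary_graph`.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  a <- graph$adjacency
  k <- rowSums(a)
  closed <- rowSums((a %*% a) * a) # = diag(A^3) = 2 t_i
  cp <- ifelse(k >= 2, closed / (k * (k - 1)), 0)
  mean(cp)
}

# All-pairs shortest-path matrix (hops); Inf between components.
graph_distances <- function(graph) {
  igraph::distances(as_igraph(graph))
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs; pairs in
#' different components are excluded (the sparsity range is chosen so that
#' networks stay in the estimable regime rather than imposing an
#' infinite-distance convention).
#'
#' @param graph A `binary_graph`.
#' @param d Optional precomputed distance matrix.
#' @return Mean finite off-diagonal distance, or `NA` if the graph has no
#'   connected pair.
#' @export
characteristic_path_length <- function(graph, d = graph_distances(graph)) {
  dv <- d[row(d) != col(d)]
  dv <- dv[is.finite(dv)]
  if (length(dv) == 0L) return(NA_real_)
  mean(dv)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs; unreachable
#' pairs contribute 0.
#'
#' @inheritParams characteristic_path_length
#' @return Value in `[0, 1]`.
#' @export
global_efficiency <- function(graph, d = graph_distances(graph)) {
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  if (n < 2L) return(0)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbor-induced
#' subgraph (the node itself excluded); nodes with fewer than two neighbors
#' contribute 0.
#'
#' @param graph A `binary_graph`.
#' @return Value in `[0, 1]`.
#' @export
local_efficiency <- function(graph) {
  a <- graph$adjacency
  vals <- vapply(seq_len(nrow(a)), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2L) return(0)
    global_efficiency(new_binary_graph(a[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

#' Degree-preserving rewired null graph
#'
#' Randomizes a graph by double-edge swaps (10 x edge-count attempted swaps),
#' preserving every node's degree exactly. Connectedness is not enforced.
#' Used to normalize clustering and path length into gamma, lambda and the
#' small-world index sigma.
#'
#' @param graph A `binary_graph` with at least 2 edges.
#' @param seed Integer seed; the rewiring is deterministic given it.
#' @return A `binary_graph` with identical degree sequence.
#' @export
rewire_null <- function(graph, seed) {
  if (graph$n_edges < 2L) {
    stop("rewire_null(): graph has fewer than 2 edges; nothing to swap",
         call. = FALSE)
  }
  set.seed(seed)
  g <- igraph::rewire(as_igraph(graph),
                      igraph::keeping_degseq(niter = 10L * graph$n_edges))
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  storage.mode(a) <- "integer"
  new_binary_graph(a)
}

#' Global network metrics with rewired-null normalization
#'
#' Computes the seven global metrics of a binary graph: clustering
#' coefficient `Cp`, characteristic path length `Lp`, global and local
#' efficiency `Eglob`/`Eloc`, and the small-world parameters
#' `gamma = Cp / <Cp_rand>`, `lambda = Lp / <Lp_rand>`, `sigma = gamma /
#' lambda`, where the null averages are over `n_nulls` degree-preserving
#' rewired graphs (null i uses seed `seed + i`, so an ensemble is exactly
#' reproducible).
#'
#' @param graph A `binary_graph` with at least one edge.
#' @param n_nulls Size of the null ensemble (>= 1).
#' @param seed Integer seed for the ensemble.
#' @return Object of class `global_metrics`: list with `Cp`, `Lp`, `gamma`,
#'   `lambda`, `sigma`, `Eglob`, `Eloc`, `connected`, `n_nulls`, and the null
#'   standard errors `gamma_se`, `lambda_se`.
#' @export
global_metrics <- function(graph, n_nulls = 100L, seed = 1L) {
  if (graph$n_edges < 1L) {
    stop("global_metrics(): graph has no edges", call. = FALSE)
  }
  if (length(n_nulls) != 1L || n_nulls < 1L) {
    stop("global_metrics(): 'n_nulls' must be at least 1", call. = FALSE)
  }
  d <- graph_distances(graph)
  cp <- clustering_coefficient(graph)
  lp <- characteristic_path_length(graph, d)
  # null i is exactly rewire_null(graph, seed + i); metrics are evaluated with
  # igraph's C routines, which agree with the package definitions (mean local
  # transitivity with degree<2 counted as 0; mean distance over connected
  # pairs) -- equivalence is enforced by the oracle test suite
  gi <- as_igraph(graph)
  swaps <- igraph::keeping_degseq(niter = 10L * graph$n_edges)
  null_cp <- numeric(n_nulls)
  null_lp <- numeric(n_nulls)
  for (b in seq_len(n_nulls)) {
    set.seed(seed + b)
    ng <- igraph::rewire(gi, swaps)
    null_cp[b] <- mean(igraph::transitivity(ng, type = "local",
                                            isolates = "zero"))
    null_lp[b] <- igraph::mean_distance(ng, directed = FALSE,
                                        unconnected = TRUE)
  }
  gamma <- cp / mean(null_cp)
  lambda <- lp / mean(null_lp, na.rm = TRUE)
  structure(list(
    Cp = cp, Lp = lp, gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    Eglob = global_efficiency(graph, d), Eloc = local_efficiency(graph),
    connected = all(is.finite(d)), n_nulls = as.integer(n_nulls),
    gamma_se = stats::sd(null_cp) / mean(null_cp)^2 * cp / sqrt(n_nulls),
    lambda_se = stats::sd(null_lp) / mean(null_lp)^2 * lp / sqrt(n_nulls)
  ), class = "global_metrics")
}

#' Nodal centrality metrics
#'
#' Degree, nodal efficiency (mean inverse distance to the other N-1 nodes,
#' 0 toward unreachable ones) and unnormalized shortest-path betweenness
#' centrality for every node.
#'
#' @param graph A `binary_graph` with at least one edge.
#' @return Object of class `nodal_metrics`: list of numeric vectors `degree`,
#'   `efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(graph) {
  if (graph$n_edges < 1L) {
    stop("nodal_metrics(): graph has no edges", call. = FALSE)
  }
  g <- as_igraph(graph)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  structure(list(
    degree = rowSums(graph$adjacency),
    efficiency = rowSums(inv) / (n - 1),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ), class = "nodal_metrics")
}

#' Area under a metric curve across the sparsity range
#'
#' Trapezoidal integral of per-threshold metric values over the sparsity
#' values of the scheme — the threshold-free summary scalar on which all
#' group inference operates.
#'
#' @param values Metric values, one per threshold.
#' @param scheme A [threshold_scheme()] (or numeric vector of sparsities).
#' @return The trapezoidal integral.
#' @export
metric_auc <- function(values, scheme = threshold_scheme()) {
  s <- if (inherits(scheme, "threshold_scheme")) scheme$s_values else scheme
  if (length(values) != length(s)) {
    stop("metric_auc(): 'values' length must match the threshold scheme",
         call. = FALSE)
  }
  if (length(s) < 2L) {
    stop("metric_auc(): at least two thresholds are required", call. = FALSE)
  }
  sum(diff(s) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Global metric curve of one similarity matrix
#'
#' Thresholds a similarity matrix at every sparsity of the scheme and computes
#' global metrics at each. With `n_nulls = 0` only the null-free metrics
#' (`Cp`, `Lp`, `Eglob`, and optionally `Eloc`) are computed, which is the
#' fast path for AUC-based group inference; with `n_nulls >= 1` the
#' rewired-null normalized `gamma`, `lambda`, `sigma` are included.
#'
#' @param matrix A `similarity_matrix` or square numeric matrix.
#' @param scheme A [threshold_scheme()].
#' @param n_nulls Null-ensemble size per threshold (0 to skip normalization).
#' @param seed Seed for the null ensembles.
#' @param local_efficiency Whether to include `Eloc`.
#' @return data.frame with one row per threshold and one column per metric.
#' @export
global_metric_curve <- function(matrix, scheme = threshold_scheme(),
                                n_nulls = 0L, seed = 1L,
                                local_efficiency = TRUE) {
  values <- as_sim_values(matrix)
  eo <- edge_order(values)
  s <- scheme$s_values
  n_t <- length(s)
  cp <- lp <- eglob <- eloc <- gam <- lam <- numeric(n_t)
  conn <- logical(n_t)
  for (t_i in seq_len(n_t)) {
    k <- edge_count_at(s[t_i], eo$n)
    take <- seq_len(min(k, length(eo$i)))
    gi <- igraph::make_empty_graph(eo$n, directed = FALSE)
    gi <- igraph::add_edges(gi, rbind(eo$i[take], eo$j[take]))
    cp[t_i] <- mean(igraph::transitivity(gi, type = "local",
                                         isolates = "zero"))
    lp[t_i] <- igraph::mean_distance(gi, directed = FALSE, unconnected = TRUE)
    eglob[t_i] <- igraph::global_efficiency(gi)
    conn[t_i] <- igraph::is_connected(gi)
    if (local_efficiency) {
      eloc[t_i] <- local_efficiency(graph_from_edges(eo, k))
    }
    if (n_nulls >= 1L) {
      swaps <- igraph::keeping_degseq(niter = 10L * k)
      null_cp <- numeric(n_nulls)
      null_lp <- numeric(n_nulls)
      for (b in seq_len(n_nulls)) {
        set.seed(seed + 1000L * t_i + b)
        ng <- igraph::rewire(gi, swaps)
        null_cp[b] <- mean(igraph::transitivity(ng, type = "local",
                                                isolates = "zero"))
        null_lp[b] <- igraph::mean_distance(ng, directed = FALSE,
                                            unconnected = TRUE)
      }
      gam[t_i] <- cp[t_i] / mean(null_cp)
      lam[t_i] <- lp[t_i] / mean(null_lp)
    }
  }
  out <- data.frame(s = s, Cp = cp, Lp = lp, Eglob = eglob, connected = conn)
  if (local_efficiency) out$Eloc <- eloc
  if (n_nulls >= 1L) {
    out$gamma <- gam
    out$lambda <- lam
    out$sigma <- gam / lam
  }
  out
}

#' Nodal metric curves and their AUCs
#'
#' Per-node degree, efficiency and betweenness at each threshold, summarized
#' by trapezoidal AUC across the sparsity range.
#'
#' @inheritParams global_metric_curve
#' @return List with `auc`: an `n_regions x 3` matrix (columns `degree`,
#'   `efficiency`, `betweenness`) and `curves`: a 3D array
#'   (threshold x region x metric).
#' @export
nodal_metric_curves <- function(matrix, scheme = threshold_scheme()) {
  graphs <- threshold_all(matrix, scheme)
  n <- graphs[[1]]$n_nodes
  mets <- c("degree", "efficiency", "betweenness")
  arr <- array(NA_real_, c(length(graphs), n, 3L),
               dimnames = list(NULL, NULL, mets))
  for (t_i in seq_along(graphs)) {
    nm <- nodal_metrics(graphs[[t_i]])
    arr[t_i, , 1] <- nm$degree
    arr[t_i, , 2] <- nm$efficiency
    arr[t_i, , 3] <- nm$betweenness
  }
  auc <- sapply(mets, function(m) {
    apply(arr[, , m, drop = FALSE], 2L, metric_auc, scheme = scheme)
  })
  labels <- if (inherits(matrix, "similarity_matrix")) matrix$region_labels
            else rownames(as_sim_values(matrix))
  if (!is.null(labels)) rownames(auc) <- labels
  list(auc = auc, curves = arr)
}

#' AUC summary of global metrics for a set of subjects
#'
#' Convenience wrapper running [global_metric_curve()] on every network and
#' integrating each metric across the sparsity range.
#'
#' @param networks Named list of `similarity_matrix` objects (e.g. from
#'   [build_cohort_networks()]).
#' @param scheme A [threshold_scheme()].
#' @param n_nulls,seed Passed to [global_metric_curve()].
#' @param local_efficiency Whether to include `Eloc`.
#' @return data.frame with one row per network: `key` plus one AUC column per
#'   metric.
#' @export
cohort_global_aucs <- function(networks, scheme = threshold_scheme(),
                               n_nulls = 0L, seed = 1L,
                               local_efficiency = TRUE) {
  rows <- lapply(seq_along(networks), function(i) {
    curve <- global_metric_curve(networks[[i]], scheme, n_nulls = n_nulls,
                                 seed = seed + 7919L * i,
                                 local_efficiency = local_efficiency)
    mets <- setdiff(colnames(curve), c("s", "connected"))
    auc <- vapply(mets, function(m) metric_auc(curve[[m]], scheme), numeric(1))
    out <- as.data.frame(as.list(auc))
    names(out) <- mets
    cbind(data.frame(key = names(networks)[i], stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}
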