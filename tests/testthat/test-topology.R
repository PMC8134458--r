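# Thresholding and graph metrics: closed-form examples, planted-edge
# recovery, rewiring invariants, AUC.

test_that("threshold_by_sparsity keeps round-half-up(s * 4005) edges on 90 nodes", {
  set.seed(1)
  v <- matrix(runif(90 * 90), 90)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  g <- threshold_by_sparsity(v, 0.10)
  expect_identical(g$n_edges, 401L)
  expect_identical(g$adjacency, t(g$adjacency))
  expect_identical(unname(diag(g$adjacency)), rep(0L, 90))
  expect_equal(g$sparsity, 401 / 4005, tolerance = 1e-12)
  expect_identical(threshold_by_sparsity(v, 0.9999)$n_edges, 4005L)
  expect_error(threshold_by_sparsity(v, 0), "0, 1")
  expect_error(threshold_by_sparsity(v, 1), "0, 1")
})

test_that("planted strongest edges are recovered exactly", {
  set.seed(2)
  n <- 20
  v <- matrix(runif(n * n, 0, 0.4), n)
  v <- (v + t(v)) / 2
  planted <- cbind(sample(n, 10), sample(n, 10))
  planted <- planted[planted[, 1] != planted[, 2], , drop = FALSE]
  v[planted] <- 0.9
  v[planted[, c(2, 1)]] <- 0.9
  diag(v) <- 1
  k <- nrow(planted)
  g <- threshold_by_sparsity(v, k / (n * (n - 1) / 2) + 1e-9)
  expect_identical(g$n_edges, as.integer(k))
  expect_true(all(g$adjacency[planted] == 1L))
})

test_that("ties break by weight then ascending row and column", {
  v <- matrix(0.2, 5, 5)
  diag(v) <- 1
  # all off-diagonal weights tied: the first k pairs in row-major order win
  g <- threshold_by_sparsity(v, 0.3)  # k = round(0.3*10) = 3
  expect_identical(g$n_edges, 3L)
  # ascending (row, column): (1,2), (1,3), (1,4) win
  expect_identical(unname(g$adjacency[1, ]), c(0L, 1L, 1L, 1L, 0L))
  expect_identical(sum(g$adjacency), 6L)
  # deterministic: same input, same graph
  expect_identical(threshold_by_sparsity(v, 0.3)$adjacency, g$adjacency)
})

test_that("global metrics match closed forms on K5 and P3", {
  k5 <- morphconn:::new_binary_graph(matrix(1L, 5, 5) - diag(1L, 5))
  gm <- global_metrics(k5, n_nulls = 2, seed = 1)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$Eglob, 1)
  expect_equal(gm$Eloc, 1)
  expect_true(gm$connected)
  p3 <- matrix(0L, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1L
  g3 <- morphconn:::new_binary_graph(p3)
  expect_equal(characteristic_path_length(g3), 4 / 3)
  expect_equal(clustering_coefficient(g3), 0)
  expect_error(global_metrics(g3, n_nulls = 0), "n_nulls")
  empty <- morphconn:::new_binary_graph(matrix(0L, 3, 3))
  expect_error(global_metrics(empty, n_nulls = 1), "no edges")
})

test_that("nodal metrics match the star-graph enumeration", {
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L
  star[2:5, 1] <- 1L
  nm <- nodal_metrics(morphconn:::new_binary_graph(star))
  expect_identical(unname(nm$degree), c(4, 1, 1, 1, 1))
  expect_equal(unname(nm$betweenness), c(6, 0, 0, 0, 0))
  expect_equal(unname(nm$efficiency), c(1, rep(0.625, 4)))
})

test_that("rewire_null preserves the degree sequence and randomizes structure", {
  set.seed(3)
  # ring lattice: each node tied to 2 neighbors either side
  n <- 24
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (s in 1:2) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  }
  ring <- morphconn:::new_binary_graph(a)
  null <- rewire_null(ring, seed = 42)
  expect_identical(rowSums(null$adjacency), rowSums(ring$adjacency))
  expect_identical(null$n_edges, ring$n_edges)
  expect_identical(rewire_null(ring, seed = 42)$adjacency, null$adjacency)
  # clustering collapses toward the random expectation for the same density
  cps <- vapply(1:20, function(b) {
    clustering_coefficient(rewire_null(ring, seed = b))
  }, numeric(1))
  expect_lt(mean(cps), clustering_coefficient(ring) / 2)
  tiny <- morphconn:::new_binary_graph(rbind(c(0L, 1L), c(1L, 0L)))
  expect_error(rewire_null(tiny, seed = 1), "fewer than 2 edges")
})

test_that("sigma is near 1 when the graph is itself a rewired-null draw", {
  set.seed(4)
  base <- morphconn:::new_binary_graph(random_adjacency(60, 300))
  g <- rewire_null(base, seed = 7)
  gm <- global_metrics(g, n_nulls = 60, seed = 11)
  expect_equal(gm$sigma, 1, tolerance = 0.15)
})

test_that("metric_auc is the trapezoidal integral over the sparsity range", {
  scheme <- threshold_scheme()
  expect_length(scheme$s_values, 25L)
  expect_equal(metric_auc(rep(2, 25), scheme), 0.48, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 25)
  expect_equal(metric_auc(ramp, scheme), 0.12, tolerance = 1e-12)
  expect_error(metric_auc(1:24, scheme), "match")
  expect_error(metric_auc(2, threshold_scheme(0.2, 0.2, 0.01)), "two thresholds")
  expect_error(threshold_scheme(0.5, 0.1), "increasing")
})

test_that("metrics are invariant under node relabeling", {
  set.seed(5)
  for (r in 1:10) {
    a <- random_adjacency(12, 20)
    g <- morphconn:::new_binary_graph(a)
    perm <- sample(12)
    gp <- morphconn:::new_binary_graph(a[perm, perm])
    expect_equal(clustering_coefficient(g), clustering_coefficient(gp),
                 tolerance = 1e-12)
    expect_equal(characteristic_path_length(g), characteristic_path_length(gp),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(g), global_efficiency(gp), tolerance = 1e-12)
    nm <- nodal_metrics(g)
    nmp <- nodal_metrics(gp)
    expect_equal(nm$degree[perm], unname(nmp$degree), tolerance = 1e-12)
    expect_equal(nm$betweenness[perm], unname(nmp$betweenness),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(6)
  for (r in 1:20) {
    a <- random_adjacency(10, 12)
    zeros <- which(upper.tri(a) & a == 0)
    add <- zeros[sample.int(length(zeros), 1)]
    a2 <- a
    a2[add] <- 1L
    a2 <- pmax(a2, t(a2))
    e1 <- global_efficiency(morphconn:::new_binary_graph(a))
    e2 <- global_efficiency(morphconn:::new_binary_graph(a2))
    expect_gte(e2, e1 - 1e-12)
  }
})

test_that("global_metric_curve aligns with per-threshold global_metrics", {
  set.seed(7)
  x <- gaussian_region_samples(seq(0.3, 0.7, length.out = 20),
                               rep(0.03, 20), 200)
  m <- build_similarity_matrix(x, region_labels = sprintf("r%02d", 1:20))
  scheme <- threshold_scheme(0.10, 0.30, 0.05)
  cur <- global_metric_curve(m, scheme)
  expect_identical(nrow(cur), 5L)
  for (t_i in c(1L, 3L, 5L)) {
    g <- threshold_by_sparsity(m, scheme$s_values[t_i])
    d <- morphconn:::graph_distances(g)
    expect_equal(cur$Cp[t_i], clustering_coefficient(g), tolerance = 1e-12)
    expect_equal(cur$Lp[t_i], characteristic_path_length(g, d),
                 tolerance = 1e-12)
    expect_equal(cur$Eglob[t_i], global_efficiency(g, d), tolerance = 1e-12)
    expect_equal(cur$Eloc[t_i], local_efficiency(g), tolerance = 1e-12)
  }
})
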