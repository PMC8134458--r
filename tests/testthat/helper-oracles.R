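# Independent brute-force oracles for graph metrics, used to validate the
# package implementations on small graphs. Deliberately written without
# igraph: Floyd-Warshall distances, explicit triangle loops, and exhaustive
# DFS path enumeration for betweenness.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_cp <- function(a) {
  n <- nrow(a)
  cp <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (u in seq_along(nb)) {
      for (v in seq_len(u - 1)) {
        if (a[nb[u], nb[v]] == 1) t_i <- t_i + 1
      }
    }
    cp[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(cp)
}

oracle_lp <- function(a) {
  d <- oracle_distances(a)
  v <- d[row(d) != col(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

oracle_eglob <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) >= 2) vals[i] <- oracle_eglob(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_nodal_efficiency <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  })
}

# Betweenness by exhaustive enumeration of all simple paths per pair:
# find the shortest length, count shortest paths, credit interior vertices
# 1/count each. Feasible for n <= 8.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  btw <- numeric(n)
  enumerate_paths <- function(current, target, visited) {
    last <- current[length(current)]
    if (last == target) return(list(current))
    out <- list()
    for (nb in which(a[last, ] == 1)) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        out <- c(out, enumerate_paths(c(current, nb), target, visited))
        visited[nb] <- FALSE
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      visited <- rep(FALSE, n)
      visited[s] <- TRUE
      paths <- enumerate_paths(s, t, visited)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      cnt <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / cnt
      }
    }
  }
  btw
}

# Random symmetric 0/1 adjacency with m edges (no self-loops).
random_adjacency <- function(n, m) {
  a <- matrix(0L, n, n)
  pick <- sample(which(upper.tri(a)), m)
  a[pick] <- 1L
  a + t(a)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- p[o] * n / seq_len(n)
  # step-up: q_(i) = min_{j >= i} adj_(j), capped at 1
  run_min <- rev(cummin(rev(adj)))
  q[o] <- pmin(run_min, 1)
  q
}

# Small Gaussian-region sample matrix for similarity tests.
gaussian_region_samples <- function(mu, sigma, n_vox = 500) {
  t(vapply(seq_along(mu),
           function(r) stats::rnorm(n_vox, mu[r], sigma[r]),
           numeric(n_vox)))
}
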