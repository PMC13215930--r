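# Independent oracles used across the suite. Each deliberately avoids the
# package's own computation path for the quantity it checks.

# Strip dimnames and bookkeeping attributes for oracle comparisons.
bare <- function(m) {
  m <- as.matrix(m)
  matrix(as.vector(m), nrow(m), ncol(m))
}

# Path-existence reachability via igraph's graph search (reflexive).
reachability_oracle <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  m <- (is.finite(d)) * 1L
  diag(m) <- 1L
  dimnames(m) <- dimnames(adjacency)
  m
}

# Longest-path-to-sink depth on the strict reduced relation (recursive).
level_oracle <- function(reduced) {
  n <- nrow(reduced)
  memo <- rep(NA_integer_, n)
  depth <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    succ <- which(reduced[i, ] == 1L)
    memo[i] <<- if (length(succ) == 0L) 1L else 1L + max(vapply(succ, depth, 0L))
    memo[i]
  }
  vapply(seq_len(n), depth, 0L)
}

# Principal eigenpair by plain power iteration.
power_iteration_oracle <- function(P, tol = 1e-14, max_iter = 100000L) {
  v <- rep(1, nrow(P))
  lambda <- 0
  for (it in seq_len(max_iter)) {
    v2 <- as.vector(P %*% v)
    lambda2 <- sum(v2) / sum(v)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol && abs(lambda2 - lambda) < tol) {
      return(list(weights = v2, lambda_max = lambda2))
    }
    v <- v2
    lambda <- lambda2
  }
  list(weights = v, lambda_max = lambda)
}

# Tucker congruence coefficient between two loading columns.
congruence <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Mean best-match congruence between recovered and planted loading matrices.
mean_congruence <- function(recovered, planted) {
  mean(vapply(seq_len(ncol(planted)), function(j) {
    max(abs(apply(recovered, 2L, congruence, y = planted[, j])))
  }, numeric(1)))
}

# Random (possibly cyclic) digraph, independent of the package's DAG generator.
random_digraph <- function(n, density, seed) {
  withr::with_seed(seed, {
    a <- matrix(as.integer(stats::runif(n * n) < density), n, n)
    diag(a) <- 0L
    a
  })
}

fixture_clusters <- function(fx = drowning_fixtures()) {
  stats::setNames(fx$factors$cluster, fx$factors$code)
}

fixture_network <- function(fx = drowning_fixtures()) {
  build_network(reachability_from_sets(fx$reachable_sets),
                fixture_clusters(fx))
}
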