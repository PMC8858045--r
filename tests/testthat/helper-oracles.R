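# Independent oracles used to freeze expected values: these deliberately use
# naive algorithms (double loops, exhaustive enumeration) so they share no
# code path with the implementation they check.

# Brute-force unsigned TOM, elementwise double loop.
tom_oracle <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  k <- colSums(A)
  out <- matrix(1, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- sum(A[i, -c(i, j)] * A[-c(i, j), j])
      out[i, j] <- (shared + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# Exhaustive upper-tail hypergeometric: P(|draw of size n from 1..N| hits
# >= k of the first K elements), by enumerating every subset.
hyper_enum_p <- function(k, K, N, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  mean(apply(draws, 2, function(s) sum(s <= K) >= k))
}

# Floyd-Warshall all-pairs shortest paths on an unweighted adjacency matrix.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (m in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  d
}

# Small deterministic expression fixture with two planted modules.
make_two_module_expr <- function(n_per_module = 30, n_bg = 20,
                                 n_samples = 20, seed = 42) {
  sim <- simulate_expression(n_genes = 2 * n_per_module + n_bg,
                             n_samples_per_condition = n_samples / 2,
                             module_sizes = rep(n_per_module, 2),
                             effect = 2, loading = 0.9, noise_sd = 0.4,
                             n_disease_modules = 1, seed = seed)
  sim
}

# Random simple graph as an igraph with named nodes (Erdos-Renyi).
random_named_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_setequal(as.character(a), as.character(b))
}
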