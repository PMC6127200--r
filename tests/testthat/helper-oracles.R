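# shared fixtures and brute-force oracles, built in code at test time

# graph from a flat vector of endpoint pairs: pair_graph("a","b", "b","c")
pair_graph <- function(...) {
  v <- c(...)
  make_network(v[seq(1, length(v), 2)], v[seq(2, length(v), 2)])
}

graph_from_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(nrow(A)))
  g
}

# random connected graph: random recursive tree plus Bernoulli extra edges
random_connected_adj <- function(n, p_extra = 0.3) {
  A <- matrix(0, n, n)
  for (t in 2:n) {
    s <- sample.int(t - 1, 1)
    A[t, s] <- A[s, t] <- 1
  }
  extra <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  add <- extra[stats::runif(nrow(extra)) < p_extra, , drop = FALSE]
  A[add] <- 1
  A[add[, c(2, 1), drop = FALSE]] <- 1
  A
}

adj_is_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# exhaustive common-neighbour + simple-length-3-path enumeration
visibility_oracle <- function(A, iota, omega = 0.01) {
  n <- nrow(A)
  k <- rowSums(A)
  eta <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cn <- which(A[i, ] > 0 & A[j, ] > 0)
      v <- if (length(cn)) sum(1 / k[cn]^iota) else 0
      p3 <- 0
      for (x in which(A[i, ] > 0)) {
        for (y in which(A[j, ] > 0)) {
          if (x != y && A[x, y] > 0 &&
              !(x %in% c(i, j)) && !(y %in% c(i, j))) {
            p3 <- p3 + 1 / (k[x] * k[y])^iota
          }
        }
      }
      eta[i, j] <- v + omega * p3
    }
  }
  eta
}

# constant-score predictor (ranking falls back to the lexicographic tie rule)
constant_predictor <- function(g, seed) {
  n <- igraph::vcount(g)
  matrix(1, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
}

# hypergeometric expectation of precision at L for a constant predictor
hyper_expected_precision <- function(n_probe, n_candidates) {
  n_probe / n_candidates
}

# uniform G(n, m) graph: edges are an exchangeable random subset of all pairs,
# the null model under which the lexicographic tie rule is unbiased. The
# vertex order is fixed a priori (not by edge appearance) so that the pair
# indexing is independent of the sampled edge set.
er_graph <- function(n, m_edges, seed) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- withr::with_seed(seed, sample.int(nrow(pairs), m_edges))
  labs <- paste0("v", seq_len(n))
  igraph::graph_from_data_frame(
    data.frame(from = labs[pairs[pick, 1]], to = labs[pairs[pick, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = labs
  )
}
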