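#' Watts-Strogatz small-world network
#'
#' Starts from a ring lattice where each node is wired to its `m_half`
#' nearest neighbours on each side (so `|E| = N * m_half` and every degree
#' is `2 * m_half`), then rewires each edge independently with probability
#' `beta`: the far endpoint is replaced by a uniformly random node that is
#' neither the near endpoint nor one of its current neighbours. Rewiring
#' preserves the edge count and keeps the graph simple.
#'
#' @param N Node count.
#' @param m_half Half the average degree; requires `2 * m_half < N`.
#' @param beta Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A simple undirected igraph graph with vertex names "1".."N" and
#'   attribute `n_rewired` giving the number of rewired edges.
#' @export
generate_ws <- function(N, m_half, beta, seed = 1L) {
  if (2 * m_half >= N) stop("need 2 * m_half < N")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  res <- withr::with_seed(seed, {
    Adj <- matrix(FALSE, N, N)
    el <- cbind(
      rep(seq_len(N), m_half),
      unlist(lapply(seq_len(m_half), function(k) ((seq_len(N) - 1 + k) %% N) + 1))
    )
    Adj[el] <- TRUE
    Adj[el[, c(2, 1)]] <- TRUE
    n_rewired <- 0L
    for (e in seq_len(nrow(el))) {
      if (stats::runif(1) < beta) {
        u <- el[e, 1]
        old <- el[e, 2]
        cand <- which(!Adj[u, ] & seq_len(N) != u)
        if (length(cand)) {
          v <- cand[sample.int(length(cand), 1L)]
          Adj[u, old] <- Adj[old, u] <- FALSE
          Adj[u, v] <- Adj[v, u] <- TRUE
          el[e, 2] <- v
          n_rewired <- n_rewired + 1L
        }
      }
    }
    list(Adj = Adj, n_rewired = n_rewired)
  })
  g <- igraph::graph_from_adjacency_matrix(res$Adj, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(N))
  attr(g, "n_rewired") <- res$n_rewired
  g
}

#' Nonuniform popularity-similarity (nPSO-style) hyperbolic network
#'
#' Growing hyperbolic model with planted angular communities. Node t
#' arrives with native radius `r_t = 2 ln(t)`; at that moment every earlier
#' node s has drifted inward to `b * r_s + (1 - b) * r_t` with popularity
#' fading `b = 1 / (gamma - 1)`, which yields a power-law degree
#' distribution of exponent `gamma`. Angular coordinates are drawn from an
#' equal-weight mixture of `n_comm` wrapped-Gaussian components with means
#' equally spaced on `[0, 2 pi)` (spread `angular_sd`), so the mixture
#' component of each node is its ground-truth community. Each new node
#' links to `m_half` existing nodes sampled without replacement with
#' weight `exp(-d / (2 T))` in the hyperbolic distance d; as `T -> 0` this
#' degenerates to the `m_half` hyperbolically closest nodes, and smaller T
#' yields higher clustering.
#'
#' @param N Node count (> `m_half`).
#' @param m_half Links added per new node (half the asymptotic mean degree).
#' @param T Temperature (> 0), inversely related to clustering.
#' @param gamma Degree-distribution exponent (> 2).
#' @param n_comm Number of angular communities (>= 1).
#' @param seed Integer seed.
#' @param angular_sd Spread of each angular component; defaults to
#'   `(2 * pi / n_comm) / 6`.
#' @return A list: `graph` (igraph, vertex names "1".."N") and `coords`, a
#'   data frame with columns node, radius, angle, community.
#' @export
generate_npso <- function(N, m_half, T, gamma = 3, n_comm = 8, seed = 1L,
                          angular_sd = (2 * pi / n_comm) / 6) {
  if (N < m_half + 1) stop("need N >= m_half + 1")
  if (T <= 0) stop("T must be > 0")
  if (gamma <= 2) stop("gamma must be > 2")
  if (n_comm < 1) stop("n_comm must be >= 1")
  withr::with_seed(seed, {
    comm <- sample.int(n_comm, N, replace = TRUE)
    centers <- 2 * pi * (comm - 1) / n_comm
    theta <- (stats::rnorm(N, centers, angular_sd)) %% (2 * pi)
    b <- 1 / (gamma - 1)
    from <- integer(0)
    to <- integer(0)
    for (t in 2:N) {
      s <- seq_len(t - 1)
      if (t <= m_half + 1) {
        targets <- s
      } else {
        rt <- 2 * log(t)
        rs <- b * 2 * log(s) + (1 - b) * rt
        dth <- pi - abs(pi - abs(theta[s] - theta[t]))
        d <- rs + rt + 2 * log(pmax(dth / 2, 1e-12))
        w <- exp(-(d - min(d)) / (2 * T))
        w <- pmax(w, 1e-300)
        targets <- s[sample.int(t - 1, m_half, prob = w)]
      }
      from <- c(from, rep(t, length(targets)))
      to <- c(to, targets)
    }
    g <- make_network(as.character(from), as.character(to))
    g <- igraph::permute(g, as.integer(igraph::V(g)$name))
    list(
      graph = g,
      coords = data.frame(
        node = as.character(seq_len(N)),
        radius = 2 * log(seq_len(N)),
        angle = theta,
        community = comm,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Write nPSO ground-truth coordinates
#'
#' Tab-separated sidecar: node, radius, angle, community.
#'
#' @param coords The `coords` data frame from [generate_npso()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
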