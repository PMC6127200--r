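#' Common-neighbours score
#'
#' `S_xy = |Gamma(x) intersect Gamma(y)|` for every node pair.
#'
#' @param g A simple undirected igraph graph.
#' @return A symmetric integer-valued score matrix with zero diagonal and
#'   vertex-name dimnames; attribute `method = "cn"`.
#' @export
cn_score <- function(g) {
  A <- adjacency_dense(g)
  S <- A %*% A
  diag(S) <- 0
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  attr(S, "method") <- "cn"
  S
}

#' Cannistraci-Hebb score
#'
#' Weights each common neighbour z of (x, y) by its local-community degree:
#' \deqn{S_{xy} = \sum_{z \in \Gamma(x) \cap \Gamma(y)}
#'   |\gamma(z)| / |\Gamma(z)|,}
#' where `gamma(z)` is the subset of z's neighbours that are themselves
#' common neighbours of x and y. Pairs without common neighbours score 0;
#' every common neighbour is adjacent to x, so its degree is positive.
#'
#' @param g A simple undirected igraph graph.
#' @return A symmetric score matrix, attribute `method = "ch"`.
#' @export
ch_score <- function(g) {
  A <- adjacency_dense(g)
  n <- nrow(A)
  deg <- rowSums(A)
  S <- matrix(0, n, n)
  if (n >= 2) {
    Al <- A > 0
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        cn <- which(Al[i, ] & Al[j, ])
        if (length(cn)) {
          gam <- rowSums(A[cn, cn, drop = FALSE])
          S[i, j] <- S[j, i] <- sum(gam / deg[cn])
        }
      }
    }
  }
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  attr(S, "method") <- "ch"
  S
}

#' Structural perturbation method score
#'
#' For each of `n_avg` rounds, a perturbation set of
#' `round(perturb_fraction * |E|)` training edges is removed, the reduced
#' adjacency `A_R = A - dA` is eigendecomposed, the removed part supplies
#' first-order eigenvalue corrections
#' `dlam_k = (x_k' dA x_k) / (x_k' x_k)`, and the perturbed reconstruction
#' `sum_k (lam_k + dlam_k) x_k x_k'` is accumulated. The score matrix is
#' the average reconstruction, read on non-adjacent pairs. A high score on
#' an unobserved pair means adding it would barely perturb the observed
#' spectral structure.
#'
#' Corrections are applied per computed eigenvector without any
#' degenerate-subspace rotation; a warning is emitted when eigenvalue gaps
#' fall below 1e-8. `perturb_fraction = 0` is accepted as the identity
#' limit (empty perturbation set), in which case the reconstruction equals
#' the adjacency matrix.
#'
#' @param g The training graph (n >= 3).
#' @param perturb_fraction Fraction of training edges in each perturbation
#'   set, in `[0, 1)`.
#' @param n_avg Number of independent perturbation rounds (>= 1).
#' @param seed Integer seed for the perturbation sampling.
#' @return A symmetric score matrix, attribute `method = "spm"`.
#' @export
spm_score <- function(g, perturb_fraction = 0.1, n_avg = 10, seed = 1L) {
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes")
  if (perturb_fraction < 0 || perturb_fraction >= 1) {
    stop("perturb_fraction must lie in [0, 1)")
  }
  if (n_avg < 1) stop("n_avg must be >= 1")
  A <- adjacency_dense(g)
  el <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  m <- nrow(el)
  n_rm <- round(perturb_fraction * m)
  if (n_rm >= m) stop("perturbation would remove all training edges")
  acc <- withr::with_seed(seed, {
    acc <- matrix(0, n, n)
    warned <- FALSE
    for (r in seq_len(n_avg)) {
      dA <- matrix(0, n, n)
      if (n_rm > 0) {
        rm_idx <- el[sample.int(m, n_rm), , drop = FALSE]
        dA[rm_idx] <- 1
        dA[rm_idx[, c(2, 1), drop = FALSE]] <- 1
      }
      ev <- eigen(A - dA, symmetric = TRUE)
      if (!warned && min(diff(sort(ev$values))) < 1e-8) {
        warning("near-degenerate eigenvalues; first-order corrections ",
                "applied per computed eigenvector", call. = FALSE)
        warned <- TRUE
      }
      dlam <- colSums(ev$vectors * (dA %*% ev$vectors)) /
        colSums(ev$vectors^2)
      acc <- acc + ev$vectors %*% ((ev$values + dlam) * t(ev$vectors))
    }
    acc
  })
  S <- acc / n_avg
  S <- (S + t(S)) / 2
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  attr(S, "method") <- "spm"
  S
}
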