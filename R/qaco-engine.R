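#' QACO parameter set
#'
#' Collects the tunable parameters of the quantum-inspired ant colony
#' optimizer. Defaults are the published operating point: pheromone seed
#' `delta = 1`, pheromone exponent `lam = 1`, visibility exponent
#' `kappa = 2`, node-intensity exponent `nu = 1`, trajectory persistence
#' `rho = 0.9`, score mixing weight `eps = 0.2`, path-of-length-3 weight
#' `omega = 0.01`, and a rotation magnitude `dtheta = 0.05 * pi`, the
#' midpoint of the admissible `[0.01 * pi, 0.08 * pi]` band.
#'
#' @param delta Initial pheromone on every node pair (> 0).
#' @param lam Exponent on the pheromone term of the transition rule.
#' @param kappa Exponent on the visibility term.
#' @param nu Exponent on the quantum node-intensity term.
#' @param rho Trajectory persistence (pheromone retained per iteration),
#'   in `[0, 1)`.
#' @param eps Weight of the visibility matrix in the final score
#'   `tau + eps * eta`.
#' @param omega Weight of the length-3-path term of the visibility index.
#' @param iota Degree-penalty exponent of the visibility index, 0 or 1.
#' @param dtheta Qubit rotation magnitude, in `[0.01 * pi, 0.08 * pi]`.
#' @param C Positive gain of the path fitness.
#' @param n_ants Number of ants `m` (at most the node count).
#' @param n_iter Number of colony iterations `N_c`.
#' @param path_len Nodes visited per ant per iteration; `NULL` means walk
#'   until the tabu list covers the whole graph.
#' @param seed Integer seed driving shuffling and walks.
#' @return A list of class `qaco_params`.
#' @export
qaco_params <- function(delta = 1, lam = 1, kappa = 2, nu = 1, rho = 0.9,
                        eps = 0.2, omega = 0.01, iota = 1,
                        dtheta = 0.05 * pi, C = 1, n_ants = 10L,
                        n_iter = 20L, path_len = NULL, seed = 1L) {
  if (delta <= 0) stop("delta must be > 0")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (!iota %in% c(0, 1)) stop("iota must be 0 or 1")
  if (dtheta < 0.01 * pi || dtheta > 0.08 * pi) {
    stop("dtheta must lie in [0.01*pi, 0.08*pi]")
  }
  if (n_ants < 1) stop("n_ants must be >= 1")
  if (n_iter < 0) stop("n_iter must be >= 0")
  if (!is.null(path_len) && path_len < 1) stop("path_len must be >= 1")
  structure(
    list(delta = delta, lam = lam, kappa = kappa, nu = nu, rho = rho,
         eps = eps, omega = omega, iota = iota, dtheta = dtheta, C = C,
         n_ants = as.integer(n_ants), n_iter = as.integer(n_iter),
         path_len = if (is.null(path_len)) NULL else as.integer(path_len),
         seed = as.integer(seed)),
    class = "qaco_params"
  )
}

# floor on |alpha|^2 so the node intensity 1/|alpha|^2 stays finite
ALPHA2_FLOOR <- 1e-6

#' Initialize the pheromone matrix
#'
#' Pheromone lives on every node pair of the completion of the graph (all
#' pairs, connected or not) and starts uniform at `delta`.
#'
#' @param n Node count (>= 2).
#' @param delta Initial pheromone (> 0).
#' @return A symmetric n x n matrix with `delta` off-diagonal, 0 diagonal.
#' @export
init_pheromone <- function(n, delta) {
  if (n < 2) stop("need n >= 2")
  if (delta <= 0) stop("delta must be > 0")
  tau <- matrix(delta, n, n)
  diag(tau) <- 0
  tau
}

#' Quasi-local visibility matrix
#'
#' For every node pair (i, j), i != j (adjacent pairs included):
#' \deqn{\eta_{ij} = \sum_{z \in \Gamma(i) \cap \Gamma(j)} k(z)^{-\iota}
#'   + \omega \sum_{i-x-y-j} (k(x)k(y))^{-\iota},}
#' where the second sum runs over simple length-3 paths i-x-y-j with
#' intermediates x, y distinct and outside \{i, j\}. Computed with dense
#' matrix products; isolated nodes never appear as intermediates so no
#' division by zero arises.
#'
#' @param g A simple undirected igraph graph.
#' @param iota Degree exponent, 0 or 1.
#' @param omega Weight of the length-3-path term (>= 0).
#' @return A symmetric non-negative matrix with zero diagonal, dimnames set
#'   to the vertex names.
#' @export
compute_visibility <- function(g, iota = 1, omega = 0.01) {
  if (!iota %in% c(0, 1)) stop("iota must be 0 or 1")
  if (omega < 0) stop("omega must be >= 0")
  A <- adjacency_dense(g)
  n <- nrow(A)
  k <- rowSums(A)
  dk <- ifelse(k > 0, 1 / k^iota, 0)
  # common-neighbour term: sum_z A_iz A_zj / k(z)^iota
  cn_term <- A %*% (dk * A)
  # length-3 paths: raw walks i-x-y-j minus those re-entering i or j
  S <- A * outer(dk, dk)           # S_xy = A_xy / (k_x k_y)^iota
  raw <- A %*% S %*% A
  dSA <- rowSums(S * A)            # diag(S %*% A), A symmetric
  p3 <- raw - A * (outer(dSA, rep(1, n)) + outer(rep(1, n), dSA)) + A * S
  eta <- cn_term + omega * p3
  eta <- (eta + t(eta)) / 2        # exact symmetry against rounding
  diag(eta) <- 0
  dimnames(eta) <- list(igraph::V(g)$name, igraph::V(g)$name)
  eta
}

#' Initialize the quantum register
#'
#' Every node carries one qubit per ant; all amplitudes start in the
#' balanced superposition `alpha = beta = 1/sqrt(2)`.
#'
#' @param n Node count.
#' @param m Ant count.
#' @return A list of class `quantum_register` with n x m matrices `alpha`
#'   and `beta`.
#' @export
init_register <- function(n, m) {
  if (n < 1 || m < 1) stop("need n >= 1 and m >= 1")
  structure(
    list(alpha = matrix(1 / sqrt(2), n, m),
         beta = matrix(1 / sqrt(2), n, m)),
    class = "quantum_register"
  )
}

#' Quantum pheromone intensity of a node
#'
#' `mu = 1 / |alpha|^2` with `|alpha|^2` floored at `1e-6` so the intensity
#' stays finite as the qubit approaches the |1> state.
#'
#' @param reg A `quantum_register`.
#' @param node Node index.
#' @param ant Ant index.
#' @return A strictly positive finite scalar.
#' @export
quantum_intensity <- function(reg, node, ant) {
  1 / pmax(reg$alpha[node, ant]^2, ALPHA2_FLOOR)
}

#' Apply the quantum rotation gate to an amplitude pair
#'
#' Rotates `(alpha, beta)` by `theta = dtheta * sign(alpha * beta)`:
#' `alpha' = cos(theta) alpha - sin(theta) beta`,
#' `beta' = sin(theta) alpha + cos(theta) beta`. The sign rule makes basis
#' states (`alpha * beta = 0`) fixed points and always grows `|beta|`
#' elsewhere, so visited nodes become more attractive. Vectorized over the
#' inputs; the norm `alpha^2 + beta^2` is preserved exactly by the rotation.
#'
#' @param alpha,beta Numeric amplitude vectors of equal length.
#' @param dtheta Rotation magnitude.
#' @return A list with rotated components `alpha` and `beta`.
#' @export
rotate_qubit <- function(alpha, beta, dtheta) {
  th <- dtheta * sign(alpha * beta)
  list(alpha = cos(th) * alpha - sin(th) * beta,
       beta = sin(th) * alpha + cos(th) * beta)
}

#' Transition distribution of an ant
#'
#' Weights every node outside the tabu set by
#' `tau_ij^lam * eta_ij^kappa * mu_j^nu` (with `0^0 := 1`) and normalizes.
#' If all weights vanish (e.g. zero visibility everywhere with
#' `kappa > 0`), falls back to the uniform distribution over candidates.
#'
#' @param current Current node index.
#' @param tabu Integer vector of already-visited nodes.
#' @param tau Pheromone matrix.
#' @param eta Visibility matrix.
#' @param reg Quantum register.
#' @param ant Ant index.
#' @param p A `qaco_params` object.
#' @return A named probability vector over candidate node indices, or
#'   `NULL` when no candidate remains (walk termination).
#' @export
transition_distribution <- function(current, tabu, tau, eta, reg, ant, p) {
  n <- nrow(tau)
  cand <- setdiff(seq_len(n), c(tabu, current))
  if (length(cand) == 0) return(NULL)
  mu <- 1 / pmax(reg$alpha[cand, ant]^2, ALPHA2_FLOOR)
  w <- tau[current, cand]^p$lam * eta[current, cand]^p$kappa * mu^p$nu
  tot <- sum(w)
  pr <- if (tot > 0) w / tot else rep(1 / length(cand), length(cand))
  names(pr) <- cand
  pr
}

#' Tabu walk of a single ant
#'
#' Starting at `start`, repeatedly samples the next node from
#' [transition_distribution()] with the visited set as tabu list, using the
#' pheromone/register state as given (frozen for the whole walk). The walk
#' ends after `steps` nodes or when no candidate remains.
#'
#' @param start Starting node index.
#' @param steps Maximum number of nodes in the path (>= 1).
#' @param tau,eta,reg,ant,p As in [transition_distribution()].
#' @return An integer vector of distinct node indices beginning at `start`.
#' @export
walk_ant <- function(start, steps, tau, eta, reg, ant, p) {
  if (steps < 1) stop("steps must be >= 1")
  n <- nrow(tau)
  steps <- min(steps, n)
  path <- integer(steps)
  path[1] <- start
  cur <- start
  len <- 1L
  while (len < steps) {
    pr <- transition_distribution(cur, path[seq_len(len)], tau, eta, reg, ant, p)
    if (is.null(pr)) break
    cand <- as.integer(names(pr))
    cur <- cand[sample.int(length(cand), 1L, prob = pr)]
    len <- len + 1L
    path[len] <- cur
  }
  path[seq_len(len)]
}

#' Fitness of an ant path
#'
#' `Q(S) = C * mean(degree)` over the path's nodes, degrees taken from the
#' training graph: paths through densely connected regions score higher.
#'
#' @param path Integer vector of node indices (nonempty).
#' @param g The training graph.
#' @param C Positive gain constant.
#' @return The fitness value.
#' @export
path_fitness <- function(path, g, C = 1) {
  if (length(path) == 0) stop("empty path has no fitness")
  C * mean(igraph::degree(g)[path])
}

#' Pheromone update
#'
#' Every pair first decays to `rho * tau`; then each ant k deposits
#' `Q_k * (1 - beta_{j,k}^2)` on every link (v_i, v_j) it traversed, where
#' `beta_{j,k}` is the destination node's k-th amplitude at iteration start.
#' Deposits are symmetric (undirected links).
#'
#' @param tau Pheromone matrix.
#' @param paths List of integer node-index paths, one per ant.
#' @param fitnesses Numeric vector, one fitness per path.
#' @param reg Quantum register at iteration start.
#' @param rho Trajectory persistence in `[0, 1)`.
#' @return The updated pheromone matrix.
#' @export
update_pheromone <- function(tau, paths, fitnesses, reg, rho) {
  if (length(paths) != length(fitnesses)) {
    stop("one fitness per path required")
  }
  tau <- rho * tau
  for (k in seq_along(paths)) {
    pth <- paths[[k]]
    if (length(pth) < 2) next
    from <- pth[-length(pth)]
    to <- pth[-1]
    dep <- fitnesses[k] * (1 - reg$beta[cbind(to, k)]^2)
    tau[cbind(from, to)] <- tau[cbind(from, to)] + dep
    tau[cbind(to, from)] <- tau[cbind(to, from)] + dep
  }
  tau
}

#' Register update
#'
#' For each ant k, the k-th qubit of every node on ant k's path is rotated
#' once by [rotate_qubit()]; all other (node, ant) qubits are unchanged.
#'
#' @param reg Quantum register.
#' @param paths List of integer node-index paths, one per ant.
#' @param dtheta Rotation magnitude.
#' @return The updated register.
#' @export
update_register <- function(reg, paths, dtheta) {
  for (k in seq_along(paths)) {
    pth <- paths[[k]]
    if (length(pth) == 0) next
    rot <- rotate_qubit(reg$alpha[pth, k], reg$beta[pth, k], dtheta)
    reg$alpha[pth, k] <- rot$alpha
    reg$beta[pth, k] <- rot$beta
  }
  reg
}

# one full walk with precomputed powers; semantics identical to walk_ant
walk_core <- function(start, steps, tauL, etaK, muNk) {
  n <- length(muNk)
  path <- integer(steps)
  path[1] <- start
  unvis <- rep(TRUE, n)
  unvis[start] <- FALSE
  cur <- start
  len <- 1L
  while (len < steps) {
    cand <- which(unvis)
    if (length(cand) == 0) break
    w <- tauL[cur, cand] * etaK[cur, cand] * muNk[cand]
    tot <- sum(w)
    pr <- if (tot > 0) w / tot else rep(1 / length(cand), length(cand))
    nxt <- cand[sample.int(length(cand), 1L, prob = pr)]
    len <- len + 1L
    path[len] <- nxt
    unvis[nxt] <- FALSE
    cur <- nxt
  }
  path[seq_len(len)]
}

#' Run the QACO link predictor
#'
#' Executes `n_iter` synchronous colony iterations on the (training) graph
#' `g`: ants are assigned to distinct nodes by shuffling the node order,
#' walk tabu paths biased by pheromone, visibility and quantum intensity,
#' and the pheromone matrix and qubit register are updated once per
#' iteration from the realized paths. The returned score matrix is
#' `tau + eps * eta`; for ranking, only pairs non-adjacent in `g` are
#' candidates. Fully reproducible from `p$seed`.
#'
#' @param g The training graph (n >= 3 nodes).
#' @param p A [qaco_params()] object with `n_ants <= n`.
#' @return A symmetric score matrix with vertex-name dimnames and
#'   attributes `method = "qaco"` and `params`.
#' @export
#' @examples
#' g <- make_network(c("a", "b", "c", "a"), c("b", "c", "d", "c"))
#' s <- run_qaco(g, qaco_params(n_ants = 2, n_iter = 5, seed = 42))
#' s["a", "d"]
run_qaco <- function(g, p = qaco_params()) {
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes")
  m <- p$n_ants
  if (m > n) stop("n_ants (", m, ") exceeds node count (", n, ")")
  eta <- compute_visibility(g, p$iota, p$omega)
  tau <- withr::with_seed(p$seed, {
    tau <- init_pheromone(n, p$delta)
    reg <- init_register(n, m)
    etaK <- eta^p$kappa
    deg <- igraph::degree(g)
    steps <- min(p$path_len %||% n, n)
    for (iter in seq_len(p$n_iter)) {
      tauL <- tau^p$lam
      muN <- (1 / pmax(reg$alpha^2, ALPHA2_FLOOR))^p$nu
      starts <- sample.int(n)[seq_len(m)]
      paths <- lapply(seq_len(m), function(k) {
        walk_core(starts[k], steps, tauL, etaK, muN[, k])
      })
      fit <- vapply(paths, function(pth) p$C * mean(deg[pth]), numeric(1))
      tau <- update_pheromone(tau, paths, fit, reg, p$rho)
      reg <- update_register(reg, paths, p$dtheta)
    }
    tau
  })
  scores <- tau + p$eps * eta
  dimnames(scores) <- list(igraph::V(g)$name, igraph::V(g)$name)
  attr(scores, "method") <- "qaco"
  attr(scores, "params") <- p
  scores
}
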