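test_that("pheromone initializes uniform, symmetric, zero-diagonal", {
  tau <- init_pheromone(3, 1)
  expect_equal(tau[upper.tri(tau)], rep(1, 3))
  expect_equal(diag(tau), rep(0, 3))
  expect_identical(tau, t(tau))
  expect_equal(init_pheromone(2, 0.5)[1, 2], 0.5)
  expect_error(init_pheromone(3, 0), "delta")
})

test_that("visibility reproduces hand-enumerated values", {
  # path a-b-c: one common neighbour of degree 2, no length-3 path
  eta <- compute_visibility(pair_graph("a", "b", "b", "c"), iota = 1)
  expect_equal(eta["a", "c"], 0.5)
  expect_equal(eta["a", "b"], 0)
  # path a-b-c-d: single simple length-3 path, intermediates of degree 2
  eta2 <- compute_visibility(pair_graph("a", "b", "b", "c", "c", "d"),
                             iota = 1, omega = 0.01)
  expect_equal(eta2["a", "d"], 0.01 * 1 / 4)
  # 4-cycle: two common neighbours, no valid simple length-3 path
  eta3 <- compute_visibility(
    pair_graph("a", "b", "b", "c", "c", "d", "d", "a"), iota = 1)
  expect_equal(eta3["a", "c"], 1)
  expect_error(compute_visibility(pair_graph("a", "b"), iota = 2), "iota")
})

test_that("visibility matches the exhaustive enumeration oracle on random graphs", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    A <- random_connected_adj(n, p_extra = stats::runif(1, 0.1, 0.6))
    g <- graph_from_adj(A)
    for (iota in c(0, 1)) {
      eta <- compute_visibility(g, iota = iota, omega = 0.01)
      expect_equal(unname(eta), visibility_oracle(A, iota, 0.01),
                   tolerance = 1e-12)
    }
  }
})

test_that("register initializes balanced and intensities follow the floored rule", {
  reg <- init_register(2, 1)
  expect_equal(reg$alpha[1, 1], 1 / sqrt(2))
  expect_equal(reg$alpha^2 + reg$beta^2, matrix(1, 2, 1), tolerance = 1e-12)
  expect_equal(quantum_intensity(reg, 1, 1), 2)
  reg$alpha[1, 1] <- 1; reg$beta[1, 1] <- 0
  expect_equal(quantum_intensity(reg, 1, 1), 1)
  reg$alpha[2, 1] <- 0; reg$beta[2, 1] <- 1
  expect_equal(quantum_intensity(reg, 2, 1), 1e6)
})

test_that("rotation gate matches analytic cases and the sign rule", {
  r <- rotate_qubit(1 / sqrt(2), 1 / sqrt(2), pi / 4)
  expect_equal(r$alpha, 0, tolerance = 1e-12)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  # basis states are fixed points (sign = 0)
  for (dt in c(0.01 * pi, 0.05 * pi, 0.08 * pi)) {
    expect_identical(rotate_qubit(1, 0, dt), list(alpha = 1, beta = 0))
    expect_identical(rotate_qubit(0, 1, dt), list(alpha = 0, beta = 1))
  }
  # negative product rotates by -dtheta: (1/sqrt(2), -1/sqrt(2)) -> (0, -1)
  r2 <- rotate_qubit(1 / sqrt(2), -1 / sqrt(2), pi / 4)
  expect_equal(r2$alpha, 0, tolerance = 1e-12)
  expect_equal(r2$beta, -1, tolerance = 1e-12)
})

test_that("rotation preserves the norm over many random applications", {
  set.seed(7)
  phi <- stats::runif(500, 0, 2 * pi)
  a <- cos(phi); b <- sin(phi)
  for (i in 1:50) {
    r <- rotate_qubit(a, b, stats::runif(1, 0.01 * pi, 0.08 * pi))
    a <- r$alpha; b <- r$beta
  }
  expect_lt(max(abs(a^2 + b^2 - 1)), 1e-9)
})

test_that("transition distributions normalize, follow the weights, and fall back", {
  p <- qaco_params()
  # symmetric triangle: uniform over the two candidates
  tau <- init_pheromone(3, 1)
  eta <- matrix(1, 3, 3); diag(eta) <- 0
  reg <- init_register(3, 1)
  pr <- transition_distribution(1, integer(0), tau, eta, reg, 1, p)
  expect_equal(unname(pr), c(0.5, 0.5))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # weights tau = (2, 1), eta = mu = 1, lam = 1 -> (2/3, 1/3)
  p1 <- qaco_params(kappa = 0, nu = 0)
  tau[1, 2] <- tau[2, 1] <- 2
  pr2 <- transition_distribution(1, integer(0), tau, eta, reg, 1, p1)
  expect_equal(unname(pr2), c(2 / 3, 1 / 3))
  # all-zero weights -> uniform over candidates
  eta0 <- matrix(0, 3, 3)
  pr3 <- transition_distribution(1, integer(0), init_pheromone(3, 1) * 0,
                                 eta0, reg, 1, p)
  expect_equal(unname(pr3), c(0.5, 0.5))
  # exhausted tabu signals termination
  expect_null(transition_distribution(1, c(2, 3), tau, eta, reg, 1, p))
})

test_that("tabu walks never revisit, stop when exhausted, and are seed-deterministic", {
  g <- generate_ws(12, 2, 0.2, seed = 1)
  eta <- compute_visibility(g)
  tau <- init_pheromone(12, 1)
  reg <- init_register(12, 3)
  p <- qaco_params(n_ants = 3)
  set.seed(99)
  path <- walk_ant(4, 12, tau, eta, reg, 2, p)
  expect_equal(anyDuplicated(path), 0)
  expect_equal(path[1], 4)
  set.seed(99)
  expect_identical(walk_ant(4, 12, tau, eta, reg, 2, p), path)
  # two-node graph: tabu exhausts candidates after 2 nodes
  tau2 <- init_pheromone(2, 1)
  eta2 <- matrix(c(0, 1, 1, 0), 2)
  reg2 <- init_register(2, 1)
  set.seed(1)
  expect_length(walk_ant(1, 5, tau2, eta2, reg2, 1, p), 2)
})

test_that("path fitness is the scaled mean training degree", {
  tri <- pair_graph("a", "b", "b", "c", "c", "a")
  expect_equal(path_fitness(c(1, 2, 3), tri, C = 1), 2)
  star <- pair_graph("c", "l1", "c", "l2", "c", "l3")
  expect_equal(path_fitness(c(1, 2, 3), star, C = 1), 5 / 3)
  expect_equal(path_fitness(c(1, 2), star, C = 0), 0)
  expect_error(path_fitness(integer(0), star), "empty")
})

test_that("pheromone update decays everywhere and deposits Q * (1 - beta^2)", {
  reg <- init_register(4, 1)
  tau <- init_pheromone(4, 1)
  # decay-only limit
  t1 <- update_pheromone(tau, list(), numeric(0), reg, 0.9)
  expect_equal(t1, 0.9 * tau)
  # single traversal with Q = 2, beta^2 = 0.5 on a unit pair
  t2 <- update_pheromone(tau, list(c(1, 2)), 2, reg, 0.9)
  expect_equal(t2[1, 2], 0.9 + 2 * 0.5)
  expect_equal(t2[2, 1], t2[1, 2])
  expect_equal(t2[3, 4], 0.9)
  expect_error(update_pheromone(tau, list(c(1, 2)), c(1, 2), reg, 0.9),
               "one fitness per path")
})

test_that("untraversed pairs decay exactly as rho^t * delta", {
  n <- 6
  reg <- init_register(n, 2)
  tau <- init_pheromone(n, 1)
  # ants walk among nodes 3..6 only, never touching pair (1, 2)
  paths <- list(c(3, 4, 5), c(5, 6, 3))
  for (t in 1:50) {
    tau <- update_pheromone(tau, paths, c(1.5, 2.5), reg, 0.9)
  }
  expect_identical(tau[1, 2], 0.9^50 * 1)
  # symmetry and non-negativity survive the updates
  expect_identical(tau, t(tau))
  expect_true(all(tau >= 0))
  expect_equal(diag(tau), rep(0, n))
})

test_that("register update rotates only visited (node, ant) qubits", {
  reg <- init_register(4, 2)
  expect_identical(update_register(reg, list(), 0.05 * pi), reg)
  upd <- update_register(reg, list(c(1, 3), integer(0)), 0.05 * pi)
  # ant-1 qubits of nodes 1 and 3 changed, all else untouched
  expect_false(upd$alpha[1, 1] == reg$alpha[1, 1])
  expect_false(upd$alpha[3, 1] == reg$alpha[3, 1])
  expect_identical(upd$alpha[c(2, 4), ], reg$alpha[c(2, 4), ])
  expect_identical(upd$alpha[, 2], reg$alpha[, 2])
  # fresh balanced qubits drift toward |1>, raising the intensity mu
  expect_lt(upd$alpha[1, 1], reg$alpha[1, 1])
  expect_gt(upd$beta[1, 1], reg$beta[1, 1])
  expect_gt(quantum_intensity(upd, 1, 1), quantum_intensity(reg, 1, 1))
  # unitarity
  expect_equal(upd$alpha^2 + upd$beta^2, matrix(1, 4, 2), tolerance = 1e-12)
})

test_that("run_qaco: zero-iteration limit, determinism, and register unitarity", {
  g <- generate_ws(15, 2, 0.1, seed = 5)
  eta <- compute_visibility(g, iota = 1, omega = 0.01)
  p0 <- qaco_params(n_ants = 5, n_iter = 0, seed = 1)
  s0 <- run_qaco(g, p0)
  exp0 <- 1 + 0.2 * eta
  diag(exp0) <- 0  # the diagonal is never a candidate pair
  expect_equal(unname(s0), unname(exp0), tolerance = 1e-14,
               ignore_attr = TRUE)
  p <- qaco_params(n_ants = 5, n_iter = 8, seed = 17)
  s1 <- run_qaco(g, p)
  s2 <- run_qaco(g, p)
  expect_identical(s1, s2)
  expect_equal(unname(s1), unname(t(s1)), ignore_attr = TRUE)
  expect_true(all(is.finite(s1)))
  expect_error(run_qaco(g, qaco_params(n_ants = 50)), "exceeds")
})

test_that("exported walk/update path reproduces the run_qaco score matrix", {
  # one full iteration executed with the granular operations under the same
  # seed must equal the driver (synchronous semantics)
  g <- generate_ws(10, 2, 0.2, seed = 2)
  n <- 10
  p <- qaco_params(n_ants = 3, n_iter = 1, seed = 31)
  eta <- compute_visibility(g, p$iota, p$omega)
  ref <- run_qaco(g, p)
  manual <- withr::with_seed(p$seed, {
    tau <- init_pheromone(n, p$delta)
    reg <- init_register(n, p$n_ants)
    starts <- sample.int(n)[seq_len(p$n_ants)]
    paths <- lapply(seq_len(p$n_ants), function(k) {
      walk_ant(starts[k], n, tau, eta, reg, k, p)
    })
    fit <- vapply(paths, path_fitness, numeric(1), g = g, C = p$C)
    tau <- update_pheromone(tau, paths, fit, reg, p$rho)
    tau + p$eps * eta
  })
  expect_equal(unname(ref), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("run time grows with network size but far slower than cubically", {
  # loose monotonicity check consistent with the O(n^2) per-iteration cost
  p <- qaco_params(n_ants = 10, n_iter = 5, seed = 1)
  t1 <- system.time(run_qaco(generate_ws(50, 3, 0.05, seed = 1), p))[["elapsed"]]
  t2 <- system.time(run_qaco(generate_ws(200, 3, 0.05, seed = 1), p))[["elapsed"]]
  expect_gt(t2, t1 * 0.5)          # bigger input is not mysteriously faster
  expect_lt(t2, max(t1, 0.02) * 64 * 4)  # and nowhere near (4x nodes)^3
})
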