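---
title: "Quantum-inspired ant colony link prediction: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired ant colony link prediction: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qacolink)
```

## The problem and the model

Given an undirected simple network `G(V, E)`, a link predictor assigns a
score to every disconnected node pair; sorting the scores puts the pairs
most likely to be true-but-unobserved links at the top. QACO treats this
as a stochastic optimization over the *completion* of `G` — the graph in
which every pair is a potential link — explored by a colony of ants.

Three coupled state variables drive the search.

**Visibility `η` (static).** For every pair `(i, j)`, adjacent or not,

$$\eta_{ij} \;=\; \sum_{z \in \Gamma(i)\cap\Gamma(j)} \frac{1}{k(z)^{\iota}}
\;+\; \omega \sum_{\substack{i-x-y-j \\ x,y \notin \{i,j\},\ x \neq y}}
\frac{1}{\left[k(x)\,k(y)\right]^{\iota}},$$

a degree-penalized common-neighbour count plus a degree-penalized count
of simple length-3 paths. With `ι = 1` this is a resource-allocation-like
weighting; `ι = 0` reduces both terms to raw path counts. The second sum
runs over *simple* paths only: walks that re-enter `i` or `j`, or reuse
an intermediate, are excluded. `compute_visibility()` evaluates this with
three dense matrix products plus two rank-one corrections that remove the
non-simple walks; the equivalence with an explicit path enumeration is
exercised over the full set of labeled connected graphs on up to five
nodes and thousands of random 6–7-node graphs in the test suite.

**Pheromone `τ` (learned).** Initialized at `δ` on every pair. Once per
iteration every entry decays to `ρ·τ` and each ant `k` deposits
`Q_k (1 - |\beta_{j,k}|^2)` on every link it traversed, where
`Q_k = C \cdot \overline{d(v)}` is the mean training-graph degree of the
ant's path. The decay law is exact: a pair never traversed holds
`ρ^t δ` after `t` iterations, bit-for-bit.

**Quantum register (learned).** Each node carries one qubit per ant,
starting in the balanced state `α = β = 1/\sqrt 2`. The node intensity
`μ = 1/|α|^2` enters the transition rule; after each iteration the qubits
on an ant's realized path are rotated by `θ = Δθ\,\mathrm{sign}(αβ)`.
The sign rule fixes the basis states and otherwise always grows `|β|`,
so visited nodes become *more* attractive (`μ` grows toward the
`1/10^{-6}` floor) while their deposits `Q(1-|\beta|^2)` shrink — a
negative feedback on pheromone concentration that counteracts the
winner-take-all dynamics of plain ant colonies.

An ant at `v_i` moves to a node `v_j` outside its tabu (visited) set with
probability proportional to `τ_{ij}^{λ}\,η_{ij}^{κ}\,μ_j^{ν}` (`0^0 := 1`).
After `N_c` iterations the score matrix is `τ + ε·η`.

## Parameters

| parameter | meaning | default | note |
|---|---|---|---|
| `delta` | initial pheromone | 1 | uniform over all pairs |
| `lam`, `kappa`, `nu` | exponents on `τ`, `η`, `μ` | 1, 2, 1 | `κ = 2` makes visibility dominate early |
| `rho` | pheromone persistence / iteration | 0.9 | in `[0, 1)` |
| `eps` | weight of `η` in the final score | 0.2 | |
| `omega` | length-3-path weight in `η` | 0.01 | |
| `iota` | degree exponent in `η` | 1 | 0 or 1, per network topology |
| `dtheta` | rotation magnitude | `0.05π` | admissible band `[0.01π, 0.08π]`; the default is its midpoint |
| `C` | fitness gain | 1 | pure gain on deposits |
| `n_ants` | colony size `m` | 10 | must not exceed `n` |
| `n_iter` | iterations `N_c` | 20 | `N_c = 0` reduces the ranking to `η` |
| `path_len` | nodes per walk | `n` | capped at `n` by the tabu rule |

The exponent/persistence defaults are the published operating point of
the algorithm; `Δθ` is only constrained to a band in the source
literature, so the package fixes its midpoint and exposes the knob.

## Numerical and semantic choices

Several points of the procedure are underdetermined and were resolved as
follows; all are locked in by tests.

- **Per-ant amplitudes.** Each node holds `m` qubits, one per ant; when
  ant `k` evaluates node `j` it reads its own amplitude `α_{j,k}`, and
  deposits use `β_{j,k}`. This keeps ants within an iteration fully
  independent ("walk without interaction").
- **Synchronous updates.** All ants of an iteration read the pheromone
  and register state frozen at the iteration start; `τ` and the register
  are updated once per iteration. The granular operations
  (`walk_ant()`, `update_pheromone()`, `update_register()`) reproduce
  `run_qaco()` exactly under a shared seed.
- **Rotation scope.** Only the `(node, ant)` qubits on that ant's
  realized path rotate, once per visit. This is the minimal reading of
  "node pheromone is updated too".
- **Zero-weight fallback.** If every candidate weight vanishes (possible
  when `η = 0` everywhere reachable and `κ > 0`), the transition falls
  back to the uniform distribution over candidates — the rule is
  otherwise 0/0 — preserving ergodicity.
- **Intensity floor.** `μ = 1/\max(|α|^2, 10^{-6})` caps the blow-up as
  a qubit approaches `|1⟩`.
- **Tie-breaking.** Rankings order by score descending, then by node
  pair lexicographically — fully deterministic, so fixed-seed runs are
  byte-identical end to end.
- **Training-graph connectivity** is *not* enforced by the edge splitter
  (nothing in the protocol requires it); probe edges whose endpoints
  become isolated remain scoreable candidates. `connected = TRUE`
  retry-samples for callers who want it.
- **SPM settings.** The structural perturbation method removes a fraction
  0.1 of training edges per round and averages 10 rounds (the customary
  settings of the method's own literature); first-order eigenvalue
  corrections are applied per computed eigenvector with no
  degenerate-subspace rotation, and a warning flags eigen-gaps below
  `10^{-8}`. `perturb_fraction = 0` is accepted as a test hook: the
  reconstruction then equals the adjacency matrix to machine precision.

## What the generators emulate

`generate_ws()` builds the classic rewired ring lattice: `m_half`
neighbours per side (`|E| = N·m_half` exactly), each edge independently
rewired with probability `beta` to a uniform non-duplicate endpoint.
At the studied settings (`N = 100..1000`, `m_half = 10..14`,
`beta = 0.001..0.1`) the graph is a near-lattice whose few rewired links
are the hard-to-predict part.

`generate_npso()` grows a hyperbolic popularity-similarity network with
planted communities: node `t` arrives at radius `2 ln t`, earlier nodes
drift inward with fading exponent `1/(γ−1)` (giving a degree power law of
exponent `γ`), angles come from an equal-weight mixture of `n_comm`
wrapped Gaussians with means equally spaced on the circle (spread
`(2π/n_comm)/6` by default), and each arrival links to `m_half` nodes
sampled by weight `e^{-d/(2T)}` in hyperbolic distance `d`. As `T → 0`
this selects the hyperbolically closest nodes; clustering falls as `T`
rises, which the tests verify at `N = 1000`. The mixture component of
each node is returned as its ground-truth community.

Neither generator reproduces the heavy tails, degree correlations or
noise of real interaction data; a pass on these testbeds demonstrates
that the machinery recovers *planted geometric structure*, not that any
particular precision carries over to a given real network.

## Evaluation protocols

Precision is measured at `L = |E^P|` per split — the same "top-r"
convention the time-evolving protocol prescribes, and the standard choice
when `L` is otherwise unspecified. Default splits per evaluation: 100
(configurable; slow predictors are commonly run at 10–20).

The null calibration of the precision metric deserves a note: with a
constant-score predictor the deterministic tie rule selects a *fixed*
window of candidate pairs, so the hypergeometric expectation
`|E^P|/\#\text{candidates}` holds only when the graph's edge placement is
exchangeable with the pair indexing. The calibration tests therefore
draw uniform `G(n, m)` graphs with an a-priori vertex order; on a
structured graph (e.g. a ring lattice, whose low-index pairs are
systematically non-edges) the constant predictor is *not* a calibrated
null — a property of the tie rule, not a bug.

Predictor comparison across networks uses midpoint-tie precision ranks
and paired sign-flip permutation tests on rank columns (each network's
two ranks swapped with probability 1/2; add-one two-sided p-value),
Benjamini–Hochberg-adjusted across all predictor pairs. The paired
scheme respects networks as blocks; the add-one estimator never returns
p = 0.

Temporal evaluation follows the top-r rule exactly: candidates at time
`i` keep only pairs whose endpoints survive to time `j`, `r` is the
number of those that are edges at `j`, and undefined cells (`r = 0`) are
skipped and excluded from the mean.

## Problem sizes and limitations

The test suite and the acceptance script run the signal-recovery
experiment at `N = 100`, `m_half = 10`, `beta = 0.01`, 50 ants, 20
iterations, 20 random 90/10 splits — a deliberately small instance of the
published experimental grid, chosen so the full suite completes in
minutes on one core; the qualitative outcome (QACO far above the random
baseline, SPM slightly ahead on rewired lattices) already shows at this
size. Dense `n × n` matrices for `τ`, `η` and the scores bound practical
use to networks of a few thousand nodes; per-iteration cost is `O(m n)`
walk steps of `O(n)` work each, consistent with the method's quadratic
overall complexity. The colony is a stochastic optimizer: per-split
precision fluctuates, and only averages over splits (the protocols
above) are meaningful summaries.
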