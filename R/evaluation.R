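#' Precision at L
#'
#' Ranks the candidate pairs of the training graph (all pairs non-adjacent
#' in it) by score, descending with deterministic tie-breaking, and returns
#' the fraction of the top L that belong to the probe set.
#'
#' @param scores Symmetric score matrix in the vertex order of the split's
#'   training graph.
#' @param split An `edge_split`.
#' @param L Number of predicted links, `1 <= L <=` number of candidates.
#' @return Precision in `[0, 1]`.
#' @export
precision_at <- function(scores, split, L) {
  tg <- train_graph(split)
  cand <- candidate_pairs(tg)
  if (L < 1 || L > nrow(cand)) {
    stop("L must lie in [1, ", nrow(cand), "]")
  }
  if (nrow(split$probe) == 0) stop("empty probe set")
  ranked <- rank_pairs(scores, cand)[seq_len(L), , drop = FALSE]
  labs <- split$labels
  n <- length(labs)
  probe_keys <- pair_key(match(split$probe[, 1], labs),
                         match(split$probe[, 2], labs), n)
  sum(pair_key(ranked[, 1], ranked[, 2], n) %in% probe_keys) / L
}

#' Evaluate a predictor over repeated random splits
#'
#' Runs `n_splits` independent train/probe splits of `g`; on each, the
#' predictor sees the training graph only and precision is measured at
#' `L = |E^P|` (the probe size) unless `L` is given. Split s uses seed
#' `seed + s - 1`, which is also handed to the predictor.
#'
#' @param g The full observed graph.
#' @param predictor A function `function(train_g, seed)` returning a score
#'   matrix; see [predictor_fun()].
#' @param fraction Training fraction (default 0.9).
#' @param n_splits Number of random splits (>= 1).
#' @param seed Base integer seed.
#' @param L Number of predicted links; `NULL` means the probe size.
#' @return An object of class `precision_result` with fields `precisions`,
#'   `mean`, `se`, `L`, `n_splits`, `fraction`, `seed`.
#' @export
evaluate_predictor <- function(g, predictor, fraction = 0.9,
                               n_splits = 100L, seed = 1L, L = NULL) {
  if (n_splits < 1) stop("n_splits must be >= 1")
  prec <- numeric(n_splits)
  Ls <- integer(n_splits)
  for (s in seq_len(n_splits)) {
    sp <- split_edges(g, fraction, seed + s - 1L)
    tg <- train_graph(sp)
    sc <- predictor(tg, seed + s - 1L)
    Ls[s] <- L %||% nrow(sp$probe)
    prec[s] <- precision_at(sc, sp, Ls[s])
  }
  structure(
    list(precisions = prec, mean = mean(prec),
         se = if (n_splits > 1) stats::sd(prec) / sqrt(n_splits) else NA_real_,
         L = Ls, n_splits = n_splits, fraction = fraction, seed = seed),
    class = "precision_result"
  )
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("precision over %d split(s): mean = %.4f (se = %.4f)\n",
              x$n_splits, x$mean, x$se))
  invisible(x)
}

#' Predictor factory
#'
#' Wraps the package's predictors into the common
#' `function(train_g, seed)` interface used by [evaluate_predictor()],
#' [evaluate_time_series()] and the command-line driver.
#'
#' @param method One of "qaco", "cn", "ch", "spm".
#' @param ... Method parameters: a [qaco_params()] object via `params` for
#'   qaco (its seed is replaced by the per-call seed), or
#'   `perturb_fraction` / `n_avg` for spm.
#' @return A predictor function.
#' @export
predictor_fun <- function(method = c("qaco", "cn", "ch", "spm"), ...) {
  method <- match.arg(method)
  dots <- list(...)
  switch(
    method,
    cn = function(g, seed) cn_score(g),
    ch = function(g, seed) ch_score(g),
    spm = function(g, seed) {
      spm_score(g,
                perturb_fraction = dots$perturb_fraction %||% 0.1,
                n_avg = dots$n_avg %||% 10, seed = seed)
    },
    qaco = function(g, seed) {
      p <- dots$params %||% qaco_params()
      p$seed <- as.integer(seed)
      run_qaco(g, p)
    }
  )
}

#' Precision-ranking table
#'
#' Within each network (row), predictors are ranked by precision in
#' descending order; tied precisions share the midpoint rank. The mean
#' ranking per predictor over all networks is the overall comparison score.
#'
#' @param table Numeric matrix of mean precisions, networks x predictors,
#'   with no missing cells.
#' @return An object of class `ranking_table`: list with `precisions`,
#'   `ranks` and `mean_ranking`.
#' @export
precision_ranking <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("precision table has missing cells")
  ranks <- t(apply(table, 1, function(x) rank(-x, ties.method = "average")))
  if (ncol(table) == 1) ranks <- matrix(1, nrow(table), 1)
  dimnames(ranks) <- dimnames(table)
  structure(
    list(precisions = table, ranks = ranks, mean_ranking = colMeans(ranks)),
    class = "ranking_table"
  )
}

#' Paired permutation test on two ranking columns
#'
#' Statistic: `|mean(col_a) - mean(col_b)|`. The null distribution is
#' generated by independently swapping each network's two ranks with
#' probability 1/2 (paired sign-flip of the differences), respecting the
#' networks-as-blocks structure. Two-sided p-value with the add-one
#' correction `(1 + #{null >= observed}) / (1 + n_iter)`.
#'
#' @param col_a,col_b Equal-length paired rank (or precision) vectors.
#' @param n_iter Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @return The p-value.
#' @export
permutation_test_rankings <- function(col_a, col_b, n_iter = 10000L,
                                      seed = 1L) {
  if (length(col_a) != length(col_b)) stop("columns must have equal length")
  if (n_iter < 1000) stop("n_iter must be >= 1000")
  d <- col_a - col_b
  obs <- abs(mean(d))
  null_ge <- withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_iter * length(d), replace = TRUE),
                    nrow = n_iter)
    null_stat <- abs(as.vector(signs %*% d) / length(d))
    sum(null_stat >= obs - 1e-12)
  })
  (1 + null_ge) / (1 + n_iter)
}

#' All pairwise permutation tests with Benjamini-Hochberg correction
#'
#' @param ranks Rank matrix (networks x predictors), e.g.
#'   `precision_ranking(x)$ranks`.
#' @param n_iter Permutations per pair.
#' @param seed Integer seed; pair p uses `seed + p - 1`.
#' @return List with symmetric matrices `p` and `p_adjusted` (BH).
#' @export
pairwise_rank_tests <- function(ranks, n_iter = 10000L, seed = 1L) {
  k <- ncol(ranks)
  if (k < 2) stop("need at least two predictors")
  P <- matrix(NA_real_, k, k, dimnames = list(colnames(ranks), colnames(ranks)))
  pair_id <- 0L
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      P[a, b] <- P[b, a] <- permutation_test_rankings(
        ranks[, a], ranks[, b], n_iter = n_iter, seed = seed + pair_id)
      pair_id <- pair_id + 1L
    }
  }
  raw <- P[upper.tri(P)]
  adj <- stats::p.adjust(raw, method = "BH")
  Padj <- P
  Padj[upper.tri(Padj)] <- adj
  Padj[lower.tri(Padj)] <- t(Padj)[lower.tri(Padj)]
  list(p = P, p_adjusted = Padj)
}

#' Time-evolving (top-r) snapshot evaluation
#'
#' For every ordered snapshot pair (i, j), i < j: the candidates are the
#' pairs non-adjacent at time i whose both endpoints still exist at time j;
#' r is the number of candidates that are edges at time j; the precision is
#' the fraction of the top-r ranked candidates that are edges at time j.
#' Cells with r = 0 are skipped with a warning and excluded from the mean.
#'
#' @param snapshots List of >= 2 named igraph graphs in time order.
#' @param predictor A `function(g, seed)` predictor; trained on snapshot i.
#' @param seed Integer seed; snapshot i uses `seed + i - 1`.
#' @return List with the upper-triangular precision `matrix` and its `mean`
#'   over defined cells.
#' @export
evaluate_time_series <- function(snapshots, predictor, seed = 1L) {
  k <- length(snapshots)
  if (k < 2) stop("need at least 2 snapshots")
  P <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    gi <- snapshots[[i]]
    sc <- predictor(gi, seed + i - 1L)
    cand <- candidate_pairs(gi)
    labs_i <- igraph::V(gi)$name
    for (j in seq.int(i + 1, k)) {
      gj <- snapshots[[j]]
      labs_j <- igraph::V(gj)$name
      keep <- labs_i[cand[, 1]] %in% labs_j & labs_i[cand[, 2]] %in% labs_j
      cj <- cand[keep, , drop = FALSE]
      if (nrow(cj) == 0) {
        warning("snapshot pair (", i, ",", j, "): no candidates, skipped")
        next
      }
      Aj <- adjacency_dense(gj)
      ii <- match(labs_i[cj[, 1]], labs_j)
      jj <- match(labs_i[cj[, 2]], labs_j)
      truth <- Aj[cbind(ii, jj)] > 0
      r <- sum(truth)
      if (r == 0) {
        warning("snapshot pair (", i, ",", j, "): no appearing links, skipped")
        next
      }
      top <- order(-sc[cj], cj[, 1], cj[, 2])[seq_len(r)]
      P[i, j] <- sum(truth[top]) / r
    }
  }
  defined <- P[upper.tri(P)]
  list(matrix = P, mean = mean(defined, na.rm = TRUE))
}
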