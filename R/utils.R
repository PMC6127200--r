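`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dense 0/1 adjacency matrix of a graph
#'
#' @param g An igraph graph.
#' @return A numeric n x n symmetric 0/1 matrix with zero diagonal, rows and
#'   columns in vertex order.
#' @export
adjacency_dense <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  storage.mode(A) <- "double"
  A[A > 1] <- 1
  diag(A) <- 0
  A
}

#' Candidate node pairs of a (training) graph
#'
#' Candidates are all unordered node pairs that are non-adjacent in `g`;
#' these are the pairs a link predictor ranks.
#'
#' @param g An igraph graph.
#' @return An integer matrix with columns `i`, `j` (vertex indices, i < j).
#' @export
candidate_pairs <- function(g) {
  A <- adjacency_dense(g)
  idx <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Rank node pairs by score
#'
#' Deterministic ordering: score descending, then first index ascending,
#' then second index ascending.
#'
#' @param scores A symmetric numeric score matrix.
#' @param pairs An integer pair matrix as from [candidate_pairs()].
#' @return `pairs` reordered by rank.
#' @export
rank_pairs <- function(scores, pairs) {
  s <- scores[pairs]
  pairs[order(-s, pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# canonical numeric key of an unordered pair, for set membership tests
pair_key <- function(i, j, n) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  (a - 1) * n + b
}

#' Write a ranked score file
#'
#' Tab-separated, one row per candidate pair (`node_u`, `node_v`, `score`)
#' sorted by descending score with deterministic tie-breaking; `#`-prefixed
#' header lines echo the predictor name and parameters.
#'
#' @param scores Symmetric score matrix with dimnames equal to the vertex
#'   names of `g`.
#' @param g The training graph defining the candidate pairs.
#' @param path Output path.
#' @param meta Named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, g, path, meta = list()) {
  cand <- candidate_pairs(g)
  ranked <- rank_pairs(scores, cand)
  labs <- igraph::V(g)$name
  hdr <- c(
    paste0("# predictor=", meta$method %||% attr(scores, "method") %||% "unknown"),
    vapply(setdiff(names(meta), "method"), function(k) {
      paste0("# ", k, "=", paste(format(meta[[k]], digits = 15), collapse = ","))
    }, character(1)),
    "# node_u\tnode_v\tscore"
  )
  body <- paste(labs[ranked[, 1]], labs[ranked[, 2]],
                format(scores[ranked], digits = 15, trim = TRUE, scientific = FALSE),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
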