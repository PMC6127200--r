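#' Read an undirected network from a plain-text edge list
#'
#' Each non-empty line holds at least two whitespace-separated node labels;
#' tokens beyond the second (e.g. weights) are ignored. Lines starting with
#' `#` or `%` are treated as comments. Duplicate lines, reversed duplicates
#' and multi-edges collapse to a single undirected edge; self-loop lines are
#' dropped with a warning. The order of first appearance of labels fixes the
#' internal vertex index.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph][igraph::igraph-package] graph with
#'   vertex names.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "b a"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g) # 2
read_edge_list <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("cannot read edge list file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- lengths(toks) < 2
  if (any(bad)) {
    stop("parse error at line ", idx[which(bad)[1]],
         ": expected at least 2 whitespace-separated tokens")
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop line(s)")
  }
  make_network(from[!loops], to[!loops])
}

#' Build a simple undirected network from endpoint label vectors
#'
#' @param from,to Character vectors of equal length giving edge endpoints.
#' @return A simple undirected named igraph graph; vertex order follows first
#'   appearance in the interleaved `from`/`to` sequence.
#' @export
make_network <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  labels <- unique(as.vector(rbind(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = labels
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a plain-text edge list
#'
#' One edge per line, endpoints in label-sorted order, lines sorted
#' lexicographically so that identical graphs serialize byte-identically.
#'
#' @param g An undirected igraph graph with vertex names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    lines <- sort(paste(el[, 1], el[, 2]))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the component with the most nodes. Ties
#' are broken deterministically in favour of the component containing the
#' lexicographically smallest vertex label.
#'
#' @param g A named igraph graph.
#' @return The induced subgraph on the largest component, vertex order
#'   preserved.
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph has no components")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    labs <- igraph::V(g)$name
    firsts <- vapply(best, function(ci) min(labs[comp$membership == ci]),
                     character(1))
    best <- best[order(firsts)[1]]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Randomly partition the edges into training and probe sets
#'
#' Draws a uniform partition without replacement: `round(fraction * |E|)`
#' edges form the training set, the rest the probe set. The split is fully
#' reproducible from `seed` and leaves the caller's RNG state untouched.
#' Training-graph connectivity is not enforced by default; `connected = TRUE`
#' retries with derived seeds until the training graph is connected.
#'
#' @param g A named igraph graph with at least 2 edges.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param connected If `TRUE`, resample (up to 100 times) until the training
#'   graph is connected.
#' @return An object of class `edge_split`: a list with character edge
#'   matrices `train` and `probe`, the `fraction`, the `seed` and the full
#'   vertex `labels` of `g`.
#' @export
split_edges <- function(g, fraction, seed, connected = FALSE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly in (0, 1)")
  }
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least 2 edges to split")
  n_train <- round(fraction * m)
  if (n_train == 0 || n_train == m) {
    stop("fraction ", fraction, " leaves an empty train or probe set for |E| = ", m)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  labels <- igraph::V(g)$name
  build <- function(s) {
    tr <- withr::with_seed(s, sample.int(m, n_train))
    structure(
      list(train = el[tr, , drop = FALSE], probe = el[-tr, , drop = FALSE],
           fraction = fraction, seed = seed, labels = labels),
      class = "edge_split"
    )
  }
  sp <- build(seed)
  if (connected) {
    tries <- 0
    while (!igraph::is_connected(train_graph(sp)) && tries < 100) {
      tries <- tries + 1
      sp <- build(seed + 1000003L * tries)
    }
    if (!igraph::is_connected(train_graph(sp))) {
      stop("could not sample a connected training graph in 100 attempts")
    }
  }
  sp
}

#' Training graph of an edge split
#'
#' Rebuilds the graph on the full node set of the original network using the
#' training edges only; nodes isolated by the split are retained so their
#' pairs remain scoreable candidates.
#'
#' @param split An `edge_split` from [split_edges()].
#' @return A named igraph graph.
#' @export
train_graph <- function(split) {
  stopifnot(inherits(split, "edge_split"))
  igraph::graph_from_data_frame(
    data.frame(from = split$train[, 1], to = split$train[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = split$labels
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat("edge_split: |train| =", nrow(x$train), "|probe| =", nrow(x$probe),
      "fraction =", x$fraction, "seed =", x$seed, "\n")
  invisible(x)
}
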