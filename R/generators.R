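## Canonical generators, perturbations and graph plumbing.
##
## All user-facing node identifiers are 0-based integers 0..n-1; internally
## igraph's 1-based vertex indices are used. Perturbations are deterministic:
## the star rewires (0,2) to (1,2), the ring rewires (0,n-1) to (1,n-1) and
## the complete graph loses edge (0,1), so that every reported value is
## reproducible without a seed.

#' Build a simple undirected graph from a 0-based edge list
#'
#' @param edges two-column matrix (or length-2k vector, read row-wise) of
#'   0-based node identifiers; may have zero rows.
#' @param n number of nodes; defaults to one more than the largest
#'   identifier referenced (0 for an empty edge list).
#' @return an \pkg{igraph} undirected graph on nodes `0..n-1`.
#' @examples
#' g <- graphFromEdgeList(rbind(c(0, 1), c(0, 2)), n = 4)
#' asEdgeList(g)
#' @export
graphFromEdgeList <- function(edges, n = NULL) {
  if (!is.matrix(edges)) {
    stopifnot(length(edges) %% 2 == 0)
    edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0) {
    if (any(edges < 0)) stop("node identifiers must be >= 0")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  if (is.null(n)) n <- if (nrow(edges)) max(edges) + 1L else 0L
  n <- as.integer(n)
  if (nrow(edges) && max(edges) >= n) stop("edge endpoint outside 0..n-1")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges + 1L))
  g
}

#' Extract the 0-based edge list of a graph
#'
#' @param g an igraph graph.
#' @return integer matrix with two columns, one row per edge.
#' @export
asEdgeList <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el - 1L
}

#' Canonical graph families
#'
#' `makeStar()` places the hub at node 0; `makeRing()` is the n-cycle;
#' `makeComplete()` connects every pair. The perturbed variants apply a
#' fixed single-edge change: `perturbStar()` rewires edge (0,2) to (1,2),
#' `perturbRing()` rewires (0,n-1) to (1,n-1) (one pendant node, one
#' degree-3 node), and `perturbComplete()` removes edge (0,1).
#'
#' @param n number of nodes. Minimum admissible order: 1 for star and
#'   complete, 3 for ring and perturbed complete, 4 for perturbed star and
#'   perturbed ring.
#' @return an igraph graph on nodes `0..n-1`.
#' @examples
#' asEdgeList(perturbStar(6))   # the 6-node rewired star
#' @export
makeStar <- function(n) {
  if (n < 1) stop("star graph requires n >= 1")
  if (n == 1) return(graphFromEdgeList(matrix(integer(0), 0, 2), n = 1))
  graphFromEdgeList(cbind(0L, 1:(n - 1L)), n = n)
}

#' @rdname makeStar
#' @export
makeRing <- function(n) {
  if (n < 3) stop("ring graph requires n >= 3")
  graphFromEdgeList(cbind(0:(n - 1L), c(1:(n - 1L), 0L)), n = n)
}

#' @rdname makeStar
#' @export
makeComplete <- function(n) {
  if (n < 1) stop("complete graph requires n >= 1")
  if (n == 1) return(graphFromEdgeList(matrix(integer(0), 0, 2), n = 1))
  graphFromEdgeList(t(utils::combn(n, 2)) - 1L, n = n)
}

#' @rdname makeStar
#' @export
perturbStar <- function(n) {
  if (n < 4) stop("perturbed star requires n >= 4")
  spokes <- setdiff(1:(n - 1L), 2L)
  graphFromEdgeList(rbind(cbind(0L, spokes), c(1L, 2L)), n = n)
}

#' @rdname makeStar
#' @export
perturbRing <- function(n) {
  if (n < 4) stop("perturbed ring requires n >= 4")
  graphFromEdgeList(rbind(cbind(0:(n - 2L), 1:(n - 1L)), c(1L, n - 1L)), n = n)
}

#' @rdname makeStar
#' @export
perturbComplete <- function(n) {
  if (n < 3) stop("perturbed complete requires n >= 3")
  el <- t(utils::combn(n, 2)) - 1L
  graphFromEdgeList(el[-1, , drop = FALSE], n = n)
}

#' Saturated nodes and the saturation operator
#'
#' A node is \emph{saturated} when it is adjacent to all other nodes
#' (degree n-1). Saturating a non-saturated node adds exactly the edges
#' needed to connect it to every other node; the input graph is unchanged
#' (igraph graphs are copied on modification).
#'
#' @param g an igraph graph.
#' @param v 0-based node identifier.
#' @return `isSaturated()` a logical; `saturateNode()` the saturated graph.
#' @examples
#' isSaturated(makeStar(5), 0)
#' asEdgeList(saturateNode(makeRing(4), 0))
#' @export
isSaturated <- function(g, v) {
  n <- igraph::vcount(g)
  if (v < 0 || v >= n) stop("unknown node: ", v)
  igraph::degree(g, v + 1L) == n - 1L
}

#' @rdname isSaturated
#' @export
saturateNode <- function(g, v) {
  n <- igraph::vcount(g)
  if (v < 0 || v >= n) stop("unknown node: ", v)
  vv <- v + 1L
  nb <- c(as.integer(igraph::neighbors(g, vv)), vv)
  missing <- setdiff(seq_len(n), nb)
  if (!length(missing)) stop("node ", v, " is already saturated")
  igraph::add_edges(g, rbind(rep(vv, length(missing)), missing))
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component. Ties
#' are broken in favor of the component containing the smallest node
#' identifier.
#'
#' @param g an igraph graph with at least one node.
#' @return an igraph graph; node identities are not preserved (the
#'   component is relabeled 0..k-1 in the original node order).
#' @export
largestComponent <- function(g) {
  if (igraph::vcount(g) < 1) stop("graph has no nodes")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) min(which(comp$membership == k)), numeric(1))
    best <- best[which.min(firsts)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Enumerate all labeled simple graphs on n nodes
#'
#' Yields all `2^(n(n-1)/2)` labeled graphs on nodes `0..n-1`, each exactly
#' once, in the deterministic order given by reading the presence bits of
#' node pairs `(0,1), (0,2), ..., (n-2,n-1)` as a binary counter. Capped at
#' n = 6 (32768 graphs) to keep exhaustive sweeps desk-scale.
#'
#' @param n node count, 1..6.
#' @return list of igraph graphs.
#' @export
enumerateLabeledGraphs <- function(n) {
  if (n < 1 || n > 6) stop("labeled-graph corpus supported for 1 <= n <= 6")
  if (n == 1) return(list(graphFromEdgeList(matrix(integer(0), 0, 2), n = 1)))
  pairs <- t(utils::combn(n, 2)) - 1L
  np <- nrow(pairs)
  bit <- 2^(0:(np - 1))
  lapply(0:(2^np - 1), function(mask) {
    graphFromEdgeList(pairs[bitwAnd(mask, bit) > 0, , drop = FALSE], n = n)
  })
}

#' Relabel a graph through a node permutation
#'
#' @param g an igraph graph on n nodes.
#' @param permutation integer vector of length n: old node `i` (0-based)
#'   becomes new node `permutation[i+1]` (0-based). Must be a bijection on
#'   `0..n-1`.
#' @return the relabeled graph (same degree multiset, isomorphic to `g`).
#' @export
relabelGraph <- function(g, permutation) {
  n <- igraph::vcount(g)
  p <- as.integer(permutation)
  if (length(p) != n || !setequal(p, seq_len(n) - 1L))
    stop("permutation must be a bijection on 0..n-1")
  igraph::permute(g, p + 1L)
}
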