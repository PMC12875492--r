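## Independent oracles and shared (memoized) heavy computations.

## Brute-force betweenness: enumerate every shortest path between every
## node pair by DFS over the BFS distance field, split pair credit evenly
## across the paths. Independent of igraph's Brandes implementation.
bruteBetweennessNormalized <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- igraph::distances(g)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- list()
    rec <- function(v, path) {
      if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
      for (w in which(A[v, ] == 1))
        if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) rec(w, c(path, w))
    }
    rec(s, s)
    k <- length(paths)
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      btw[inner] <- btw[inner] + 1 / k
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

## Gini coefficient from the sorted-degree formulation (no double sum).
sortedGiniNGC <- function(g) {
  n <- igraph::vcount(g)
  d <- sort(igraph::degree(g))
  if (n < 3 || sum(d) == 0) return(0)
  gini <- 2 * sum(seq_len(n) * d) / (n^2 * mean(d)) - (n + 1) / n
  gini / ((n - 2) / n)
}

## Principal eigenvector by shifted power iteration from the uniform
## vector: A + I keeps the principal eigenspace and makes it strictly
## dominant (also over the -lambda_1 branch of bipartite components), and
## the uniform start converges to the projection onto that eigenspace.
powerIterationEV <- function(g, iters = 5000L) {
  A <- as.matrix(igraph::as_adjacency_matrix(g)) + diag(igraph::vcount(g))
  v <- rep(1, nrow(A)) / sqrt(nrow(A))
  for (i in seq_len(iters)) {
    w <- A %*% v
    w <- w / sqrt(sum(w * w))
    if (max(abs(w - v)) < 1e-13) { v <- w; break }
    v <- w
  }
  as.numeric(pmax(v, 0) / sqrt(sum(pmax(v, 0)^2)))
}

## Maximum population degree variance over all labeled graphs on n nodes,
## by direct bitmask enumeration (no igraph, no measure code).
bruteMaxDegreeVariance <- function(n) {
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  best <- 0
  for (mask in 0:(2^np - 1)) {
    on <- bitwAnd(mask, 2^(0:(np - 1))) > 0
    d <- tabulate(c(pairs[on, 1], pairs[on, 2]), nbins = n)
    best <- max(best, sum((d - mean(d))^2) / n)
  }
  best
}

## Seeded random connected-ish small graphs for oracle comparisons.
randomSmallGraphs <- function(k, nRange = 4:6, seed = 404) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    n <- sample(nRange, 1)
    pairs <- t(utils::combn(n, 2)) - 1L
    keep <- runif(nrow(pairs)) < 0.5
    graphFromEdgeList(pairs[keep, , drop = FALSE], n = n)
  })
}

## ---------------------------------------------------------------------
## Memoized heavy objects, shared across test files in one session.
## ---------------------------------------------------------------------
.cache <- new.env(parent = emptyenv())

sharedAxiomBattery <- function() {
  if (is.null(.cache$ax)) .cache$ax <- runAxiomBattery(seed = 1L)
  .cache$ax
}

sharedNumericalBattery <- function() {
  if (is.null(.cache$nm)) .cache$nm <- runNumericalBattery()
  .cache$nm
}

sharedCorpus <- function() {
  if (is.null(.cache$corpus))
    .cache$corpus <- unlist(lapply(1:5, enumerateLabeledGraphs),
                            recursive = FALSE)
  .cache$corpus
}

sharedCorpusValues <- function() {
  if (is.null(.cache$vals)) {
    vals <- t(vapply(sharedCorpus(), function(g) as.numeric(measureAll(g)),
                     numeric(11)))
    colnames(vals) <- centralizationMeasures()
    .cache$vals <- vals
  }
  .cache$vals
}

## Largest |change| of any measure under 5 seeded relabelings of every
## corpus graph (NA cells, i.e. NCC on disconnected graphs, are skipped).
sharedIsoMaxDelta <- function() {
  if (is.null(.cache$isoDelta)) {
    corpus <- sharedCorpus()
    vals <- sharedCorpusValues()
    set.seed(99)
    delta <- 0
    for (i in seq_along(corpus)) {
      n <- igraph::vcount(corpus[[i]])
      if (n < 2) next
      for (k in 1:5) {
        p <- sample.int(n) - 1L
        vp <- as.numeric(measureAll(relabelGraph(corpus[[i]], p)))
        dd <- abs(vp - vals[i, ])
        delta <- max(delta, dd[!is.na(dd)])
      }
    }
    .cache$isoDelta <- delta
  }
  .cache$isoDelta
}
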