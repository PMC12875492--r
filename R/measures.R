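## The eleven normalized centralization measures and their ingredients.
##
## Every measure maps a simple undirected graph to [0,1], with degenerate
## conventions (tiny n, empty edge set) pinned so that the minimal-
## centralization postulates hold where the literature records compliance.
## Shortest-path machinery comes from igraph; the normalizations, spectral
## summaries and degenerate conventions are defined here.

#' Measure identifiers
#'
#' The eleven measure ids, alphabetically: ABH (assortativity-based
#' hubness), ECD (eigenvector centrality dispersion), NBC (normalized
#' betweenness centralization), NCC (normalized closeness centralization),
#' NDC (normalized degree centralization), NDE (normalized degree entropy),
#' NDV (normalized degree variance), NGC (normalized Gini coefficient),
#' NHD (normalized hub dominance), NHT (normalized hub formation tendency),
#' NNC (normalized natural connectivity).
#'
#' @return character vector of the eleven ids.
#' @export
centralizationMeasures <- function() {
  c("ABH", "ECD", "NBC", "NCC", "NDC", "NDE", "NDV", "NGC", "NHD", "NHT", "NNC")
}

#' Numerical tolerance used when comparing a measure against 0 or 1
#'
#' Rational-arithmetic measures use 1e-9; the two eigendecomposition-based
#' measures (ECD, NNC) use 1e-6.
#'
#' @param id measure id.
#' @return a positive numeric tolerance.
#' @export
measureTolerance <- function(id) {
  id <- match.arg(id, centralizationMeasures())
  if (id %in% c("ECD", "NNC")) 1e-6 else 1e-9
}

#' Degree statistics of a graph
#'
#' Shared ingredient of the degree-based measures: the degree vector,
#' extremes, mean, population variance, histogram over degree values
#' 0..n-1, and the degree assortativity coefficient r, computed as the
#' Pearson correlation of endpoint-degree pairs over both orientations of
#' every edge. When either marginal has zero variance (every edge joins
#' equal-degree nodes, e.g. any regular graph), r is defined as 1; for
#' m = 0 the coefficient is undefined (`assortativityDefined = FALSE`) and
#' consumers apply their own conventions.
#'
#' @param g an igraph graph.
#' @return a list with elements `degrees`, `dmax`, `meanDegree`,
#'   `variance`, `histogram` (counts `n_k` for k = 0..n-1), `assortativity`
#'   and `assortativityDefined`.
#' @examples
#' degreeStats(makeStar(5))$assortativity   # exactly -1
#' @export
degreeStats <- function(g) {
  n <- igraph::vcount(g)
  d <- if (n) igraph::degree(g) else numeric(0)
  hist <- if (n) tabulate(d + 1L, nbins = n) else integer(0)
  list(
    degrees = d,
    dmax = if (n) max(d) else 0,
    meanDegree = if (n) mean(d) else 0,
    variance = if (n) sum((d - mean(d))^2) / n else 0,
    histogram = hist,
    assortativity = .assortativity(g, d),
    assortativityDefined = igraph::ecount(g) > 0
  )
}

## Pearson correlation of endpoint degrees over both edge orientations;
## 1 by convention when the marginals are constant, NA when m = 0.
.assortativity <- function(g, d = igraph::degree(g)) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  el <- igraph::as_edgelist(g, names = FALSE)
  x <- c(d[el[, 1]], d[el[, 2]])
  y <- c(d[el[, 2]], d[el[, 1]])
  if (stats::var(x) == 0) return(1)
  stats::cor(x, y)
}

#' Normalized per-node centrality vectors
#'
#' `betweennessNormalized()` divides raw shortest-path betweenness
#' (endpoints excluded) by `(n-1)(n-2)/2`; it is defined on disconnected
#' graphs, where unreachable pairs contribute nothing.
#' `closenessNormalized()` computes `(n-1) / sum_j dist(i, j)` and requires
#' a connected graph (extract the largest component first for disconnected
#' input). `eigenvectorCentrality()` returns the nonnegative, L2-normalized
#' principal eigenvector of the adjacency matrix, computed as the
#' projection of the uniform vector onto the principal eigenspace so that
#' the result is deterministic and relabeling-invariant even when the
#' spectral radius is shared by several components.
#'
#' @param g an igraph graph. Minimum order: 3 for betweenness and
#'   closeness; 2 nodes and 1 edge for the eigenvector.
#' @return a list with elements `kind`, `values` (per node, in node
#'   order), `max` and `mean`.
#' @examples
#' betweennessNormalized(makeStar(5))$values    # center 1, leaves 0
#' @export
betweennessNormalized <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) stop("betweenness centralization requires n >= 3")
  v <- igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  list(kind = "betweenness", values = v, max = max(v), mean = mean(v))
}

#' @rdname betweennessNormalized
#' @export
closenessNormalized <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) stop("closeness centralization requires n >= 3")
  if (!igraph::is_connected(g))
    stop("closeness is undefined on disconnected graphs; extract the largest component first")
  v <- (n - 1) / rowSums(igraph::distances(g))
  list(kind = "closeness", values = v, max = max(v), mean = mean(v))
}

#' @rdname betweennessNormalized
#' @export
eigenvectorCentrality <- function(g) {
  if (igraph::vcount(g) < 2) stop("eigenvector centrality requires n >= 2")
  if (igraph::ecount(g) < 1) stop("eigenvector centrality requires m >= 1")
  v <- .principalEigenvector(g)
  list(kind = "eigenvector", values = v, max = max(v), mean = mean(v))
}

## Projection of the all-ones vector onto the eigenspace of the largest
## adjacency eigenvalue, L2-normalized. The Perron vectors of the
## components attaining the spectral radius all have positive overlap with
## the uniform vector, so the projection is nonzero and permutation-
## equivariant; entries are clamped at 0 to absorb eigensolver noise.
.principalEigenvector <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A, symmetric = TRUE)
  top <- which(e$values > e$values[1] - 1e-9)
  V <- e$vectors[, top, drop = FALSE]
  v <- as.numeric(V %*% crossprod(V, rep(1, nrow(A))))
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12) {  # unreachable for symmetric 0/1 adjacency; guard anyway
    v <- abs(e$vectors[, 1])
    nv <- sqrt(sum(v * v))
  }
  v <- pmax(v / nv, 0)
  v / sqrt(sum(v * v))
}

#' Adjacency spectrum and natural connectivity
#'
#' Natural connectivity is the logarithm of the average exponentiated
#' adjacency eigenvalue, `ln((1/n) sum_i exp(lambda_i))`, evaluated with a
#' numerically stable log-sum-exp so that orders in the hundreds do not
#' overflow. The complete-graph reference at the same order,
#' `ln((e^(n-1) + (n-1) e^(-1)) / n)`, is the maximum over graphs of that
#' order and anchors the NNC normalization.
#'
#' @param g an igraph graph with at least one node.
#' @return a list with `eigenvalues` (decreasing), `naturalConnectivity`
#'   and `completeReference`.
#' @examples
#' spectralSummary(makeComplete(4))$naturalConnectivity  # log((exp(3)+3*exp(-1))/4)
#' @export
spectralSummary <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1) stop("spectral summary requires n >= 1")
  lam <- if (igraph::ecount(g) == 0) rep(0, n) else
    eigen(as.matrix(igraph::as_adjacency_matrix(g)), symmetric = TRUE,
          only.values = TRUE)$values
  list(
    eigenvalues = lam,
    naturalConnectivity = .logSumExp(lam) - log(n),
    completeReference = .completeNaturalConnectivity(n)
  )
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

.completeNaturalConnectivity <- function(n) {
  if (n < 2) return(0)
  .logSumExp(c(n - 1, rep(-1, n - 1))) - log(n)
}

## ---------------------------------------------------------------------
## The measures. `.computeMeasures()` evaluates any subset on one graph,
## sharing the degree vector and the eigendecomposition across measures;
## the exported single-measure functions are thin wrappers over it.
## ---------------------------------------------------------------------

.computeMeasures <- function(g, ids = centralizationMeasures(),
                             nccAsNA = FALSE) {
  bad <- setdiff(ids, centralizationMeasures())
  if (length(bad)) stop("unknown measure id: ", paste(bad, collapse = ", "))
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  d <- if (n) igraph::degree(g) else numeric(0)
  dmax <- if (n) max(d) else 0
  dbar <- if (n) mean(d) else 0
  out <- stats::setNames(numeric(length(ids)), ids)
  degen <- stats::setNames(logical(length(ids)), ids)
  for (id in ids) {
    val <- switch(id,
      ABH = if (n < 2 || m == 0) { degen[id] <- TRUE; 0 } else
        (1 - .assortativity(g, d)) / 2,
      ECD = if (n < 2 || m == 0) { degen[id] <- TRUE; 0 } else {
        ce <- .principalEigenvector(g)
        (sum((ce - mean(ce))^2) / n) / ((n - 1) / n^2)
      },
      NBC = if (n < 3) { degen[id] <- TRUE; 0 } else {
        cb <- igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
        sum(max(cb) - cb) / (n - 1)
      },
      NCC = if (n < 3 || m == 0) { degen[id] <- TRUE; 0 }
        else if (!igraph::is_connected(g)) {
          if (!nccAsNA)
            stop("NCC is undefined on disconnected graphs; extract the largest component first")
          NA_real_
        } else {
          cc <- (n - 1) / rowSums(igraph::distances(g))
          (2 * n - 3) * sum(max(cc) - cc) / ((n - 1) * (n - 2))
        },
      NDC = if (n < 3) { degen[id] <- TRUE; 0 } else
        n * (dmax - dbar) / ((n - 1) * (n - 2)),
      NDE = if (n < 2) { degen[id] <- TRUE; 0 } else {
        p <- as.numeric(table(d)) / n
        -sum(p * log(p)) / log(n)
      },
      NDV = if (n < 3) { degen[id] <- TRUE; 0 } else {
        dvmax <- max((n - 1) * (n - 2)^2 / n^2,
                     ((2 * n^3 - 6 * n) - (4 * n - 6)^2) / n^2)
        (sum((d - dbar)^2) / n) / dvmax
      },
      NGC = if (n < 3 || m == 0) { degen[id] <- TRUE; 0 } else {
        sum(abs(outer(d, d, "-"))) / (2 * n^2 * dbar) / ((n - 2) / n)
      },
      NHD = if (n < 2 || m == 0) { degen[id] <- TRUE; 0 } else dmax / (n - 1),
      NHT = if (n < 2 || m == 0) { degen[id] <- TRUE; 0 } else
        (sum(d^2) / sum(d)) / ((m + 1) / 2),
      NNC = if (m == 0) { degen[id] <- TRUE; 0 } else {
        lam <- eigen(as.matrix(igraph::as_adjacency_matrix(g)),
                     symmetric = TRUE, only.values = TRUE)$values
        lmax <- .completeNaturalConnectivity(n)
        (lmax - (.logSumExp(lam) - log(n))) / lmax
      }
    )
    out[id] <- val
  }
  attr(out, "degenerate") <- degen
  out
}

#' The eleven normalized centralization measures
#'
#' Each function maps a simple undirected igraph graph to a value in
#' \[0, 1\]. Formulas (d_i the degree of node i, n nodes, m edges):
#'
#' \describe{
#'   \item{`abh`}{`(1 - r)/2` with r the degree assortativity over edge
#'     endpoints; 0 when n < 2 or m = 0; r := 1 for regular-endpoint
#'     (zero-variance) graphs, so regular graphs score 0 and stars 1.}
#'   \item{`ecd`}{variance of the L2-normalized eigenvector centrality over
#'     nodes, divided by its maximum `(n-1)/n^2`; 0 when n < 2 or m = 0.}
#'   \item{`nbc`}{`sum_i (CB* - CB(i)) / (n-1)` on normalized betweenness;
#'     0 when n < 3; defined on disconnected graphs.}
#'   \item{`ncc`}{`(2n-3) sum_i (CC* - CC(i)) / ((n-1)(n-2))` on normalized
#'     closeness; 0 when n < 3 or m = 0; errors on other disconnected
#'     input.}
#'   \item{`ndc`}{Freeman degree centralization
#'     `n (dmax - mean(d)) / ((n-1)(n-2))`; 0 when n < 3.}
#'   \item{`nde`}{Shannon entropy of the degree histogram over ln(n);
#'     0 when n < 2.}
#'   \item{`ndv`}{population degree variance over its maximum, attained by
#'     the star for n < 7 and by the two-hub graph for n >= 7; 0 when
#'     n < 3.}
#'   \item{`ngc`}{Gini coefficient of the degree sequence over its maximum
#'     `(n-2)/n` (attained by one edge plus isolated nodes); 0 when n < 3
#'     or m = 0.}
#'   \item{`nhd`}{hub dominance `dmax/(n-1)`; 0 when n < 2 or m = 0.}
#'   \item{`nht`}{hub formation tendency
#'     `(sum d^2 / sum d) / ((m+1)/2)`; 0 when n < 2 or m = 0.}
#'   \item{`nnc`}{`(lmax - natural connectivity)/lmax` with lmax the
#'     complete-graph natural connectivity at the same n; 0 when m = 0.}
#' }
#'
#' @param g an igraph graph.
#' @return a single numeric value in \[0, 1\].
#' @examples
#' ndc(perturbStar(6))   # 0.7
#' ngc(makeStar(10))     # 0.5
#' @export
abh <- function(g) unname(.computeMeasures(g, "ABH")[1])

#' @rdname abh
#' @export
ecd <- function(g) unname(.computeMeasures(g, "ECD")[1])

#' @rdname abh
#' @export
nbc <- function(g) unname(.computeMeasures(g, "NBC")[1])

#' @rdname abh
#' @export
ncc <- function(g) unname(.computeMeasures(g, "NCC")[1])

#' @rdname abh
#' @export
ndc <- function(g) unname(.computeMeasures(g, "NDC")[1])

#' @rdname abh
#' @export
nde <- function(g) unname(.computeMeasures(g, "NDE")[1])

#' @rdname abh
#' @export
ndv <- function(g) unname(.computeMeasures(g, "NDV")[1])

#' @rdname abh
#' @export
ngc <- function(g) unname(.computeMeasures(g, "NGC")[1])

#' @rdname abh
#' @export
nhd <- function(g) unname(.computeMeasures(g, "NHD")[1])

#' @rdname abh
#' @export
nht <- function(g) unname(.computeMeasures(g, "NHT")[1])

#' @rdname abh
#' @export
nnc <- function(g) unname(.computeMeasures(g, "NNC")[1])

#' Evaluate several measures on one graph
#'
#' Shared ingredients (degrees, eigendecomposition) are computed once. NCC
#' on a disconnected graph is reported as `NA` (undefined) rather than
#' silently skipped or errored, so batch pipelines can record it.
#'
#' @param g an igraph graph.
#' @param measures subset of [centralizationMeasures()].
#' @return named numeric vector, one entry per requested measure, with a
#'   logical attribute `degenerate` flagging values produced by a small-n
#'   or empty-graph convention.
#' @examples
#' measureAll(makeRing(10), c("NBC", "NCC", "NDC"))
#' @export
measureAll <- function(g, measures = centralizationMeasures()) {
  .computeMeasures(g, measures, nccAsNA = TRUE)
}
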