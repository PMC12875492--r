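edgeKey <- function(g) {
  el <- asEdgeList(g)
  paste(sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))),
        collapse = ";")
}

test_that("star, ring and complete generators have the defining degree structure", {
  for (n in c(4, 6, 9)) {
    s <- makeStar(n)
    d <- igraph::degree(s)
    expect_equal(igraph::ecount(s), n - 1)
    expect_equal(sum(d == n - 1), 1)
    expect_equal(d[1], n - 1)        # hub at node 0
    expect_true(all(d[-1] == 1))
  }
  expect_equal(igraph::vcount(makeStar(1)), 1)
  expect_equal(igraph::ecount(makeStar(1)), 0)

  for (n in c(3, 5, 8)) {
    r <- makeRing(n)
    expect_equal(igraph::ecount(r), n)
    expect_true(all(igraph::degree(r) == 2))
  }
  expect_equal(edgeKey(makeRing(4)), edgeKey(graphFromEdgeList(c(0,1, 1,2, 2,3, 3,0))))

  for (n in c(2, 4, 5)) {
    k <- makeComplete(n)
    expect_equal(igraph::ecount(k), n * (n - 1) / 2)
    expect_true(all(vapply(0:(n - 1), function(v) isSaturated(k, v), logical(1))))
  }

  expect_error(makeStar(0), "n >= 1")
  expect_error(makeRing(2), "n >= 3")
  expect_error(makeComplete(0), "n >= 1")
})

test_that("perturbations apply the fixed single-edge change", {
  expect_equal(edgeKey(perturbStar(6)),
               edgeKey(graphFromEdgeList(c(0,1, 0,3, 0,4, 0,5, 1,2))))
  expect_equal(edgeKey(perturbStar(4)),
               edgeKey(graphFromEdgeList(c(0,1, 0,3, 1,2))))
  p10 <- perturbStar(10)
  expect_equal(max(igraph::degree(p10)), 8)
  expect_equal(igraph::degree(p10)[3], 1)   # node 2 rewired onto node 1
  expect_equal(igraph::ecount(p10), 9)

  pr <- perturbRing(5)
  expect_equal(sort(igraph::degree(pr)), c(1, 2, 2, 2, 3))
  expect_equal(edgeKey(perturbRing(4)),
               edgeKey(graphFromEdgeList(c(0,1, 1,2, 2,3, 1,3))))
  pr20 <- perturbRing(20)
  expect_equal(igraph::ecount(pr20), 20)
  expect_equal(max(igraph::degree(pr20)), 3)

  pc <- perturbComplete(10)
  expect_equal(sort(unique(igraph::degree(pc))), c(8, 9))
  expect_equal(igraph::ecount(perturbComplete(4)), 5)
  expect_equal(sort(igraph::degree(perturbComplete(3))), c(1, 1, 2))  # path

  expect_error(perturbStar(3), "n >= 4")
  expect_error(perturbRing(3), "n >= 4")
  expect_error(perturbComplete(2), "n >= 3")
})

test_that("saturation adds exactly the missing edges and leaves the input intact", {
  g <- graphFromEdgeList(c(0,1, 0,3, 0,4, 0,5, 1,2))
  y <- saturateNode(g, 3)
  expect_equal(igraph::ecount(g), 5)        # input untouched
  expect_equal(igraph::ecount(y), 9)
  added <- setdiff(strsplit(edgeKey(y), ";")[[1]], strsplit(edgeKey(g), ";")[[1]])
  expect_setequal(added, c("1 3", "2 3", "3 4", "3 5"))
  expect_true(isSaturated(y, 3))

  empty3 <- graphFromEdgeList(matrix(integer(0), 0, 2), n = 3)
  expect_equal(edgeKey(saturateNode(empty3, 0)), edgeKey(makeStar(3)))

  ring4sat <- saturateNode(makeRing(4), 0)
  expect_equal(setdiff(strsplit(edgeKey(ring4sat), ";")[[1]],
                       strsplit(edgeKey(makeRing(4)), ";")[[1]]), "0 2")

  expect_error(saturateNode(makeStar(5), 0), "already saturated")
  expect_error(saturateNode(makeStar(5), 7), "unknown node")
  expect_false(isSaturated(makeStar(5), 1))
  expect_true(isSaturated(makeStar(5), 0))
})

test_that("largest component extraction follows size then smallest-id tie-break", {
  g <- graphFromEdgeList(c(0,1, 1,2, 3,4), n = 5)
  igraph::V(g)$label <- as.character(0:4)
  lcc <- largestComponent(g)
  expect_equal(igraph::vcount(lcc), 3)
  expect_setequal(igraph::V(lcc)$label, c("0", "1", "2"))

  conn <- makeRing(6)
  expect_equal(edgeKey(largestComponent(conn)), edgeKey(conn))

  iso <- graphFromEdgeList(matrix(integer(0), 0, 2), n = 5)
  igraph::V(iso)$label <- as.character(0:4)
  expect_equal(igraph::V(largestComponent(iso))$label, "0")

  tie <- graphFromEdgeList(c(1,2, 3,4), n = 5)   # two 2-node components
  igraph::V(tie)$label <- as.character(0:4)
  expect_setequal(igraph::V(largestComponent(tie))$label, c("1", "2"))

  expect_error(largestComponent(graphFromEdgeList(matrix(integer(0), 0, 2), n = 0)),
               "no nodes")
})

test_that("labeled-graph enumeration is complete and duplicate-free", {
  expect_length(enumerateLabeledGraphs(2), 2)
  expect_length(enumerateLabeledGraphs(3), 8)
  g4 <- enumerateLabeledGraphs(4)
  expect_length(g4, 64)
  expect_equal(anyDuplicated(vapply(g4, edgeKey, character(1))), 0L)
  expect_length(enumerateLabeledGraphs(5), 1024)
  expect_error(enumerateLabeledGraphs(7), "1 <= n <= 6")
  expect_error(enumerateLabeledGraphs(0), "1 <= n <= 6")
})

test_that("relabeling permutes edges and preserves the degree multiset", {
  g <- makeStar(4)
  expect_equal(edgeKey(relabelGraph(g, 0:3)), edgeKey(g))
  swapped <- relabelGraph(g, c(1L, 0L, 2L, 3L))
  expect_equal(igraph::degree(swapped)[2], 3)   # hub moved to node 1
  expect_equal(edgeKey(swapped), edgeKey(graphFromEdgeList(c(1,0, 1,2, 1,3))))

  r <- makeRing(5)
  rot <- relabelGraph(r, c(1:4, 0L))
  expect_equal(sort(igraph::degree(rot)), sort(igraph::degree(r)))
  expect_equal(igraph::ecount(rot), 5)

  expect_error(relabelGraph(g, c(0L, 0L, 1L, 2L)), "bijection")
  expect_error(relabelGraph(g, 0:2), "bijection")
})

test_that("the edge-list constructor enforces graph invariants", {
  expect_error(graphFromEdgeList(c(0, 0)), "self-loops")
  expect_error(graphFromEdgeList(c(0,1, 1,0)), "duplicate")
  expect_error(graphFromEdgeList(c(0,1), n = 1), "outside")
  expect_error(graphFromEdgeList(c(-1, 2)), ">= 0")
  g <- graphFromEdgeList(matrix(integer(0), 0, 2), n = 3)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(asEdgeList(makeStar(3)), rbind(c(0L, 1L), c(0L, 2L)))
})
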