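pstar6 <- graphFromEdgeList(c(0,1, 0,3, 0,4, 0,5, 1,2))
path3 <- graphFromEdgeList(c(0,1, 1,2))
path4 <- graphFromEdgeList(c(0,1, 1,2, 2,3))
oneEdge5 <- graphFromEdgeList(c(0, 1), n = 5)
empty <- function(n) graphFromEdgeList(matrix(integer(0), 0, 2), n = n)

test_that("degree statistics expose the shared ingredients, assortativity included", {
  ds <- degreeStats(pstar6)
  expect_equal(ds$dmax, 4)
  expect_equal(ds$meanDegree, 5 / 3)
  expect_equal(ds$histogram, c(0, 4, 1, 0, 1, 0))  # n_k over k = 0..5
  expect_equal(sum(ds$histogram), 6)
  expect_equal(sum(ds$degrees), 2 * igraph::ecount(pstar6))

  expect_equal(degreeStats(makeStar(5))$assortativity, -1)
  expect_equal(degreeStats(path4)$assortativity, -0.5)
  expect_equal(degreeStats(makeRing(6))$assortativity, 1)  # regular convention
  expect_false(degreeStats(empty(3))$assortativityDefined)
  ## cross-check the generic case against igraph's assortativity
  g <- graphFromEdgeList(c(0,1, 0,2, 0,3, 1,2, 3,4))
  expect_equal(degreeStats(g)$assortativity,
               igraph::assortativity_degree(g), tolerance = 1e-12)
})

test_that("normalized betweenness matches its closed forms and handles disconnection", {
  expect_equal(betweennessNormalized(makeStar(5))$values, c(1, 0, 0, 0, 0))
  expect_equal(betweennessNormalized(path3)$values, c(0, 1, 0))
  expect_equal(betweennessNormalized(makeComplete(5))$values, rep(0, 5))
  disc <- graphFromEdgeList(c(0,1, 1,2, 3,4), n = 5)
  expect_equal(betweennessNormalized(disc)$values, c(0, 1 / 6, 0, 0, 0))
  expect_error(betweennessNormalized(makeComplete(2)), "n >= 3")
})

test_that("normalized closeness matches its closed forms and rejects disconnected input", {
  expect_equal(closenessNormalized(makeComplete(4))$values, rep(1, 4))
  expect_equal(closenessNormalized(makeStar(5))$values, c(1, rep(4 / 7, 4)))
  expect_error(closenessNormalized(graphFromEdgeList(c(0,1, 2,3))), "disconnected")
  expect_error(closenessNormalized(makeComplete(2)), "n >= 3")
})

test_that("eigenvector centrality is the L2-normalized principal eigenvector", {
  expect_equal(eigenvectorCentrality(makeComplete(5))$values, rep(1 / sqrt(5), 5))
  expect_equal(eigenvectorCentrality(oneEdge5)$values,
               c(1 / sqrt(2), 1 / sqrt(2), 0, 0, 0), tolerance = 1e-9)
  expect_equal(eigenvectorCentrality(makeStar(5))$values,
               c(1 / sqrt(2), rep(1 / (2 * sqrt(2)), 4)), tolerance = 1e-9)
  expect_error(eigenvectorCentrality(empty(5)), "m >= 1")
  expect_error(eigenvectorCentrality(empty(1)), "n >= 2")
})

test_that("spectral summary computes natural connectivity stably", {
  s <- spectralSummary(empty(3))
  expect_equal(s$naturalConnectivity, 0)
  k4 <- spectralSummary(makeComplete(4))
  expect_equal(k4$naturalConnectivity, log((exp(3) + 3 * exp(-1)) / 4))
  expect_equal(k4$naturalConnectivity, k4$completeReference)
  expect_equal(spectralSummary(makeComplete(2))$naturalConnectivity, log(cosh(1)))
  expect_equal(sum(spectralSummary(makeRing(6))$eigenvalues), 0, tolerance = 1e-9)
  ## log-sum-exp must survive orders where exp(n-1) overflows
  expect_true(is.finite(spectralSummary(makeComplete(800))$naturalConnectivity))
})

test_that("each measure reproduces its reference values", {
  # ABH
  expect_equal(abh(graphFromEdgeList(c(0,1, 0,2), n = 4)), 1)
  expect_equal(abh(makeRing(6)), 0)
  expect_equal(abh(path4), 0.75)
  # ECD
  expect_equal(ecd(makeComplete(5)), 0, tolerance = 1e-9)
  expect_equal(ecd(oneEdge5), 0.75, tolerance = 1e-9)   # (n-2)/(n-1)
  expect_equal(ecd(empty(4)), 0)
  # NBC
  expect_equal(nbc(pstar6), 0.82)
  expect_equal(nbc(makeRing(10)), 0)
  expect_equal(nbc(path3), 1)
  # NCC
  expect_equal(ncc(makeStar(7)), 1)
  expect_equal(ncc(makeComplete(6)), 0)
  expect_equal(ncc(path3), 1)
  expect_error(ncc(graphFromEdgeList(c(0,1, 2,3))), "disconnected")
  # NDC
  expect_equal(ndc(pstar6), 0.7)
  expect_equal(ndc(saturateNode(pstar6, 3)), 0.6)
  expect_equal(ndc(makeStar(9)), 1)
  # NDE
  expect_equal(nde(makeRing(8)), 0)
  expect_equal(nde(makeStar(10)),
               -(0.1 * log(0.1) + 0.9 * log(0.9)) / log(10))
  expect_equal(nde(empty(1)), 0)
  # NDV
  expect_equal(ndv(makeStar(5)), 1)
  expect_equal(ndv(makeStar(7)), 0.9375)   # (150/49)/(160/49): two-hub branch
  expect_equal(ndv(makeRing(10)), 0)
  # NGC
  expect_equal(ngc(makeStar(12)), 0.5)
  expect_equal(ngc(oneEdge5), 1)
  expect_equal(ngc(makeComplete(6)), 0)
  # NHD
  expect_equal(nhd(makeStar(8)), 1)
  expect_equal(nhd(makeComplete(20)), 1)
  expect_equal(nhd(makeRing(21)), 0.1)
  # NHT
  expect_equal(nht(makeStar(9)), 1)
  expect_equal(nht(makeComplete(5)), 8 / 11)
  expect_equal(nht(oneEdge5), 1)
  # NNC
  expect_equal(nnc(makeComplete(6)), 0, tolerance = 1e-9)
  expect_equal(nnc(empty(4)), 0)
  expect_equal(nnc(makeComplete(2)), 0, tolerance = 1e-9)  # K2 natural connectivity is the reference
})

test_that("degenerate conventions return zero below each measure's domain", {
  one <- empty(1)
  for (id in centralizationMeasures())
    expect_equal(as.numeric(measureAll(one, id)), 0, label = id)
  e4 <- empty(4)
  v <- measureAll(e4)
  expect_true(all(v == 0))
  ## the m = 0 conventions fire and are flagged; the degree-only measures
  ## evaluate to 0 without needing one
  expect_true(all(attr(v, "degenerate")[c("ABH", "ECD", "NCC", "NGC",
                                          "NHD", "NHT", "NNC")]))
  expect_equal(abh(makeComplete(2)), 0)   # K2 is regular: r := 1
})

test_that("measureAll shares ingredients and reports undefined NCC explicitly", {
  v <- measureAll(makeStar(6))
  expect_equal(v[["NDC"]], 1)
  expect_equal(v[["NGC"]], 0.5)
  expect_equal(v[["NHD"]], 1)
  expect_equal(v[["NHT"]], 1)
  expect_equal(v[["ABH"]], 1)
  z <- measureAll(makeRing(10), c("NBC", "NCC", "NDC"))
  expect_equal(as.numeric(z), c(0, 0, 0))
  d <- measureAll(graphFromEdgeList(c(0,1, 2,3)), c("NBC", "NCC"))
  expect_true(is.na(d[["NCC"]]))
  expect_false(is.na(d[["NBC"]]))
  expect_error(measureAll(makeStar(4), "XYZ"), "unknown measure")
})
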