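test_that("the two-group toy reproduces the bundled fixture at size 6", {
  toy <- generateTwoGroupToy()
  expect_equal(numNodes(toy$network), 13)
  key <- function(net) {
    ed <- edgeTable(net)
    sort(paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v)))
  }
  expect_identical(key(toy$network), key(loadFixture("twogroup13")))
  expect_identical(overlappingNodes(toy$truth), "7")
})

test_that("the toy's connector is electrically central but betweenness-blind", {
  for (m in c(5, 6, 8)) {
    toy <- generateTwoGroupToy(groupSize = m)
    expect_equal(numNodes(toy$network), 2 * m + 1)
    connector <- overlappingNodes(toy$truth)
    b <- scores(shortestPathBetweenness(toy$network))
    expect_equal(unname(b[connector]), 0)
    C <- scores(currentFlowCentrality(toy$network))
    expect_gt(C[[connector]], 0)
  }
  expect_error(generateTwoGroupToy(2), "at least 3")
})

test_that("the toy is mirror-symmetric between its two groups", {
  toy <- generateTwoGroupToy()
  C <- scores(currentFlowCentrality(toy$network))
  mirror <- c(`1` = "11", `2` = "10", `3` = "12", `4` = "9", `5` = "13",
              `6` = "8")
  for (i in names(mirror))
    expect_equal(C[[i]], C[[mirror[[i]]]], tolerance = 1e-10)
})

test_that("without connectors or background the communities are the components", {
  pl0 <- generatePlantedNetwork(nCommunities = 3, communitySizes = c(6, 6, 6),
                                nBridging = 0, nOverlapping = 0, pIn = 0.9,
                                pOut = 0, seed = 4)
  comp <- igraph::components(asIgraph(pl0$network))
  expect_equal(comp$no, 3)
  memb <- membership(pl0$truth)
  split1 <- unname(split(nodes(pl0$network), comp$membership[nodes(pl0$network)]))
  split2 <- unname(split(names(memb), unlist(memb)))
  expect_setequal(lapply(split1, sort), lapply(split2, sort))
})

test_that("planted structure: memberships, cross degrees, determinism", {
  pl <- generatePlantedNetwork(seed = 21)
  net <- pl$network; tr <- pl$truth
  ed <- edgeTable(net)
  memb <- membership(tr)
  commOf <- function(x) memb[[x]][1]

  for (bn in bridgingNodes(tr)) {
    cross <- sum((ed$u == bn & vapply(ed$v, commOf, 0L) != commOf(bn)) |
                 (ed$v == bn & vapply(ed$u, commOf, 0L) != commOf(bn)))
    expect_equal(cross, 2)   # exactly bridgingOutDegree cross edges
  }
  for (ov in overlappingNodes(tr)) {
    hosts <- memb[[ov]]
    expect_length(hosts, 2)
    nb <- c(ed$v[ed$u == ov], ed$u[ed$v == ov])
    perHost <- table(vapply(nb, commOf, 0L))
    expect_true(all(perHost[as.character(hosts)] >= 4))
  }

  pl2 <- generatePlantedNetwork(seed = 21)
  expect_identical(edgeTable(pl2$network), edgeTable(net))

  # denser inside than across (background off: cross only via connectors)
  members <- setdiff(nodes(net), overlappingNodes(tr))
  sameComm <- vapply(seq_len(nrow(ed)), function(r) {
    cu <- memb[[ed$u[r]]]; cv <- memb[[ed$v[r]]]
    length(intersect(cu, cv)) > 0
  }, TRUE)
  expect_gt(mean(sameComm), 0.9)
})

test_that("planted generation rejects infeasible specifications", {
  expect_error(generatePlantedNetwork(pIn = 0.2, pOut = 0.3), "exceed")
  expect_error(generatePlantedNetwork(communitySizes = c(2, 25, 25, 25)),
               "at least 3")
  expect_error(generatePlantedNetwork(overlapDegreePerCommunity = 40),
               "exceeds")
})

test_that("the disconnected regime without connectors is the community partition", {
  pl <- generatePlantedNetwork(nCommunities = 2, communitySizes = c(8, 8),
                               pIn = 0.9, pOut = 0, nBridging = 1,
                               bridgingOutDegree = 2, nOverlapping = 0,
                               seed = 8)
  comp <- igraph::components(asIgraph(pl$network))
  expect_equal(comp$no, 1)  # the single bridging node joins the two blocks
})

test_that("LFR-style generation respects mixing, truncation and seeding", {
  lfr <- generateLfrLike(n = 150, mu = 0, seed = 31)
  memb <- membership(lfr$truth)
  ed <- edgeTable(lfr$network)
  cross <- vapply(seq_len(nrow(ed)), function(r)
    memb[[ed$u[r]]] != memb[[ed$v[r]]], TRUE)
  expect_false(any(cross))

  lfr2 <- generateLfrLike(n = 150, mu = 0, seed = 31)
  expect_identical(edgeTable(lfr2$network), edgeTable(lfr$network))

  deg <- table(factor(c(ed$u, ed$v), levels = nodes(lfr$network)))
  expect_lte(max(deg), floor(sqrt(150)))
})

test_that("LFR-style degrees follow the requested power-law exponent", {
  lfr <- generateLfrLike(n = 1000, tau1 = 2, seed = 17)
  ed <- edgeTable(lfr$network)
  deg <- as.integer(table(factor(c(ed$u, ed$v),
                                 levels = nodes(lfr$network))))
  deg <- deg[deg >= 2]
  alpha <- oraclePowerLawExponent(deg, kMin = 2, kMax = floor(sqrt(1000)))
  expect_lt(abs(alpha - 2), 0.3)
})
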