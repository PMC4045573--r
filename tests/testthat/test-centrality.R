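test_that("node throughflow: interior half-sum, fixed endpoints, dead ends", {
  net <- mkNet(c("s", "m", "m"), c("m", "t", "d"))  # path plus dead end d
  pf <- solveUndirected(net, "s", "t")
  ft <- edgeCurrents(net, pf)
  expect_equal(nodeThroughflow(net, ft, "m"), 1, tolerance = 1e-9)
  expect_equal(nodeThroughflow(net, ft, "s"), 1)
  expect_equal(nodeThroughflow(net, ft, "t"), 1)
  expect_equal(nodeThroughflow(net, ft, "d"), 0, tolerance = 1e-12)
  expect_error(nodeThroughflow(net, ft, "zz"), "unknown")
})

test_that("current-flow centrality is symmetric on automorphism orbits", {
  tri <- mkNet(c("a", "b", "c"), c("b", "c", "a"))
  s <- scores(currentFlowCentrality(tri))
  expect_equal(max(s) - min(s), 0, tolerance = 1e-12)
})

test_that("current-flow centrality matches the brute-force pair-loop oracle", {
  for (seed in 1:10) {
    n <- sample(4:8, 1)
    net <- randomConnectedNet(n, 0.5, seed = 100 + seed)
    expect_equal(scores(currentFlowCentrality(net)), oracleCFC(net),
                 tolerance = 1e-8, label = paste("seed", seed))
  }
})

test_that("centrality from the Jacobi route agrees with the production path", {
  net <- randomConnectedNet(8, 0.4, seed = 5)
  nd <- nodes(net)
  n <- length(nd)
  acc <- stats::setNames(numeric(n), nd)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    pf <- solveUndirected(net, nd[a], nd[b], method = "jacobi", tol = 1e-12)
    ft <- edgeCurrents(net, pf)
    for (i in nd) acc[i] <- acc[i] + nodeThroughflow(net, ft, i)
  }
  expect_equal(acc / (n * (n - 1) / 2), scores(currentFlowCentrality(net)),
               tolerance = 1e-6)
})

test_that("the two-group example ranks its connector above betweenness's view", {
  net <- loadFixture("twogroup13")
  C <- scores(currentFlowCentrality(net))
  expect_lt(max(abs(C[c("3", "4", "9", "12")] - 0.279)), 1e-3)
  expect_lt(max(abs(C[c("1", "2", "10", "11")] - 0.238)), 1e-3)
  expect_lt(abs(C[["7"]] - 0.308), 1e-3)
  ranking <- names(sort(C, decreasing = TRUE))
  expect_setequal(ranking[1:2], c("6", "8"))
  expect_setequal(ranking[3:4], c("5", "13"))
  expect_equal(ranking[5], "7")
})

test_that("directed centrality respects symmetry and the diode oracle", {
  # single arc s -> t with unit ground branches, solved by hand:
  # source s gives V = (2/3, 1/3), so t's throughflow is (1/3 + 1/3)/2;
  # source t blocks the arc entirely, giving s throughflow 0
  two <- mkNet("s", "t", directed = TRUE)
  s2 <- scores(directedCurrentFlowCentrality(two))
  expect_equal(s2[["s"]], (1 + 0) / 2, tolerance = 1e-9)
  expect_equal(s2[["t"]], (1 / 3 + 1) / 2, tolerance = 1e-9)

  cyc <- mkNet(c("a", "b", "c"), c("b", "c", "a"), directed = TRUE)
  sc <- scores(directedCurrentFlowCentrality(cyc))
  expect_equal(max(sc) - min(sc), 0, tolerance = 1e-9)

  dag <- mkNet(c("a", "a", "b", "c"), c("b", "c", "d", "d"), directed = TRUE)
  nd <- nodes(dag)
  ed <- edgeTable(dag)
  expected <- stats::setNames(numeric(4), nd)
  for (src in nd) {
    V <- oracleDirectedPotentials(dag, src)
    f <- pmax(0, ed$conductance * (V[ed$u] - V[ed$v]))
    gf <- V  # unit ground conductance
    for (i in nd) {
      expected[i] <- expected[i] + if (i == src) 1 else
        0.5 * (sum(f[ed$u == i | ed$v == i]) + gf[[i]])
    }
  }
  expect_equal(scores(directedCurrentFlowCentrality(dag)), expected / 4,
               tolerance = 1e-8)
})

test_that("accumulated flows reflect symmetry, bridges and transitivity", {
  path <- mkNet(c("s", "m"), c("m", "t"))
  Tacc <- flows(accumulateEdgeFlows(path))
  expect_equal(Tacc[["s|m"]], Tacc[["m|t"]], tolerance = 1e-9)

  # barbell: two K4 blocks joined by one bridge carries the maximum T
  blk <- t(utils::combn(4, 2))
  u <- c(paste0("a", blk[, 1]), paste0("b", blk[, 1]), "a1")
  v <- c(paste0("a", blk[, 2]), paste0("b", blk[, 2]), "b1")
  barbell <- mkNet(u, v)
  Tb <- flows(accumulateEdgeFlows(barbell))
  expect_equal(names(which.max(Tb)), "a1|b1")

  # complete graph: edge-transitive, all T equal
  k5 <- mkNet(paste0("n", t(utils::combn(5, 2))[, 1]),
              paste0("n", t(utils::combn(5, 2))[, 2]))
  Tk <- flows(accumulateEdgeFlows(k5))
  expect_equal(max(Tk) - min(Tk), 0, tolerance = 1e-9)
})

test_that("directed accumulation merges opposite arcs by adding currents", {
  # a <-> b plus b -> c
  net <- mkNet(c("a", "b", "b"), c("b", "a", "c"), directed = TRUE)
  ft <- accumulateEdgeFlows(net)
  ed <- edgeTable(ft)
  expect_equal(nrow(ed), 2)            # a|b merged, b|c
  expect_true(all(ed$flow >= 0))
  # the merged a|b entry equals the sum of both arcs' accumulated flows
  nd <- nodes(net)
  edn <- edgeTable(net)
  total <- 0
  for (src in nd) {
    V <- voltages(solveDirected(net, src))
    f <- pmax(0, edn$conductance * (V[edn$u] - V[edn$v]))
    total <- total + sum(f[(edn$u == "a" & edn$v == "b") |
                           (edn$u == "b" & edn$v == "a")])
  }
  expect_equal(ed$flow[ed$u == "a" & ed$v == "b"], total, tolerance = 1e-9)
})

test_that("betweenness matches the path-enumeration oracle and edge cases", {
  p3 <- mkNet(c("a", "b"), c("b", "c"))
  b3 <- scores(shortestPathBetweenness(p3))
  expect_gt(b3[["b"]], 0)
  expect_equal(unname(b3[c("a", "c")]), c(0, 0))

  for (seed in 1:5) {
    net <- randomConnectedNet(7, 0.4, seed = 200 + seed)
    expect_equal(scores(shortestPathBetweenness(net)), oracleBetweenness(net),
                 tolerance = 1e-9, label = paste("seed", seed))
  }

  two <- mkNet("a", "b")
  expect_equal(unname(scores(shortestPathBetweenness(two))), c(0, 0))
})

test_that("centrality is invariant under node relabeling", {
  net <- randomConnectedNet(8, 0.4, seed = 9)
  s1 <- scores(currentFlowCentrality(net))
  ed <- edgeTable(net)
  perm <- stats::setNames(paste0("y", rev(nodes(net))), nodes(net))
  rel <- conductanceNetwork(
    data.frame(u = perm[ed$u], v = perm[ed$v], conductance = ed$conductance),
    nodes = unname(perm[nodes(net)]))
  s2 <- scores(currentFlowCentrality(rel))
  expect_equal(unname(s2[perm[names(s1)]]), unname(s1), tolerance = 1e-10)
})

test_that("disconnected input is scored within components", {
  net <- mkNet(c("a", "b", "c", "x", "y", "z"),
               c("b", "c", "a", "y", "z", "x"))
  s <- scores(currentFlowCentrality(net))
  expect_equal(max(s) - min(s), 0, tolerance = 1e-12)  # two equal triangles
})
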