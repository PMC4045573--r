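test_that("series resistors carry the full current and add voltage drops", {
  net <- mkNet(c("s", "m"), c("m", "t"))
  for (method in c("direct", "jacobi")) {
    pf <- solveUndirected(net, "s", "t", method = method, tol = 1e-12)
    V <- voltages(pf)
    expect_equal(unname(V["s"] - V["t"]), 2, tolerance = 1e-9)
    f <- flows(edgeCurrents(net, pf))
    expect_equal(unname(f), c(1, 1), tolerance = 1e-9)
    expect_lt(pf@residual, 1e-10)
  }
})

test_that("equal parallel paths split the current evenly", {
  net <- mkNet(c("s", "a", "s", "b"), c("a", "t", "b", "t"))
  pf <- solveUndirected(net, "s", "t")
  f <- flows(edgeCurrents(net, pf))
  expect_equal(unname(abs(f)), rep(0.5, 4), tolerance = 1e-9)
})

test_that("an edge between equipotential nodes carries no current", {
  # square s-a-t-b with a rung a-b: V_a = V_b by symmetry
  net <- mkNet(c("s", "a", "s", "b", "a"), c("a", "t", "b", "t", "b"))
  pf <- solveUndirected(net, "s", "t")
  f <- flows(edgeCurrents(net, pf))
  expect_equal(unname(f["a|b"]), 0, tolerance = 1e-12)
})

test_that("direct, Jacobi and the pseudoinverse oracle agree on random graphs", {
  for (seed in 1:5) {
    net <- randomConnectedNet(6, 0.5, seed = seed)
    pf1 <- solveUndirected(net, "1", "6", method = "direct")
    pf2 <- solveUndirected(net, "1", "6", method = "jacobi", tol = 1e-11)
    expect_lt(max(abs(voltages(pf1) - voltages(pf2))), 10 * 1e-10)
    Vo <- oraclePotentials(net, "1", "6")
    expect_equal(voltages(pf1), Vo, tolerance = 1e-8)
    expect_equal(unname(flows(edgeCurrents(net, pf1))),
                 unname(oracleEdgeFlows(net, Vo)), tolerance = 1e-8)
  }
})

test_that("solver rejects bad configurations and reports non-convergence", {
  net <- mkNet(c("a", "c"), c("b", "d"))   # two components
  expect_error(solveUndirected(net, "a", "c"), "different connected components")
  expect_error(solveUndirected(net, "a", "a"), "differ")
  expect_error(solveUndirected(net, "a", "nope"), "unknown")
  path <- mkNet(c("s", "m"), c("m", "t"))
  expect_error(solveUndirected(path, "s", "t", method = "jacobi", maxIter = 2),
               "converge")
})

test_that("undirected solutions obey conservation, scaling and relabeling", {
  for (seed in 1:4) {
    net <- randomConnectedNet(7, 0.4, seed = 10 + seed)
    pf <- solveUndirected(net, "2", "5")
    f <- edgeCurrents(net, pf)
    ed <- edgeTable(f)
    signedAt <- function(node)
      sum(ed$flow[ed$u == node]) - sum(ed$flow[ed$v == node])
    expect_equal(signedAt("2"), 1, tolerance = 1e-9)
    expect_equal(signedAt("5"), -1, tolerance = 1e-9)
    for (x in setdiff(nodes(net), c("2", "5")))
      expect_lt(abs(signedAt(x)), 1e-9)

    # conductance scaling leaves currents unchanged
    ed0 <- edgeTable(net)
    scaled <- conductanceNetwork(transform(ed0, conductance = conductance * 3),
                                 nodes = nodes(net))
    fs <- flows(edgeCurrents(scaled, solveUndirected(scaled, "2", "5")))
    expect_equal(fs, flows(f), tolerance = 1e-9)

    # relabeling commutes with solving
    perm <- stats::setNames(paste0("x", rev(nodes(net))), nodes(net))
    rel <- conductanceNetwork(
      data.frame(u = perm[ed0$u], v = perm[ed0$v],
                 conductance = ed0$conductance),
      nodes = unname(perm[nodes(net)]))
    Vr <- voltages(solveUndirected(rel, perm[["2"]], perm[["5"]]))
    expect_equal(unname(Vr[perm[nodes(net)]]), unname(voltages(pf)),
                 tolerance = 1e-9)
  }
})

test_that("exchanging which endpoint is grounded only shifts the potential", {
  net <- randomConnectedNet(6, 0.5, seed = 3)
  V1 <- voltages(solveUndirected(net, "1", "4"))
  V2 <- voltages(solveUndirected(net, "4", "1"))  # reversed injection
  expect_equal(V1 - V1["1"], -(V2 - V2["1"]), tolerance = 1e-9)
})

test_that("a forward diode conducts and a reverse diode blocks", {
  fwd <- mkNet("s", "t", directed = TRUE)
  pf <- solveDirected(fwd, "s")
  ft <- edgeCurrents(fwd, pf)
  expect_gt(flows(ft)[["s|t"]], 0)
  V <- voltages(pf)
  expect_true(V["t"] > 0 && V["t"] < V["s"])

  rev <- mkNet("t", "s", directed = TRUE)
  pf2 <- solveDirected(rev, "s")
  ft2 <- edgeCurrents(rev, pf2)
  expect_equal(flows(ft2)[["t|s"]], 0)
  expect_equal(unname(ft2@groundFlows["s"]), 1, tolerance = 1e-9)
})

test_that("directed solutions match the exhaustive diode-state oracle", {
  for (seed in 1:6) {
    net <- randomDirectedNet(4, 5, seed = seed)
    src <- nodes(net)[1]
    Vo <- oracleDirectedPotentials(net, src)
    for (method in c("direct", "relaxation")) {
      pf <- solveDirected(net, src, method = method, tol = 1e-11)
      expect_equal(voltages(pf), Vo, tolerance = 1e-6,
                   label = paste("seed", seed, method))
      # no arc ever carries negative current
      expect_true(all(flows(edgeCurrents(net, pf)) >= 0))
      # all injected current leaves through the ground branches
      expect_equal(sum(edgeCurrents(net, pf)@groundFlows), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("directed solver validates its arguments", {
  net <- mkNet("s", "t", directed = TRUE)
  expect_error(solveDirected(net, "s", groundConductance = 0), "groundConductance")
  expect_error(solveDirected(net, "nope"), "unknown source")
  undirected <- mkNet("s", "t")
  expect_error(solveDirected(undirected, "s"), "directed")
  expect_error(solveUndirected(net, "s", "t"), "undirected")
})
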