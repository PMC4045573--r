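#' Current flow through one node for a single configuration
#'
#' Kirchhoff's law makes the current entering a node equal the current
#' leaving it, so for an interior node the current passing through it is
#' half the sum of the absolute currents on its incident edges (the ground
#' branch counts as incident in the directed circuit). The flows through the
#' source and target themselves are fixed at the injected current.
#'
#' @param net The solved \linkS4class{ConductanceNetwork}.
#' @param flowTable An \linkS4class{EdgeFlowTable} in
#'   \code{signed_single_pair} mode.
#' @param node Node label.
#' @return Non-negative numeric scalar (amperes).
#' @export
nodeThroughflow <- function(net, flowTable, node) {
  stopifnot(is(net, "ConductanceNetwork"), is(flowTable, "EdgeFlowTable"))
  if (flowTable@mode != "signed_single_pair")
    stop("nodeThroughflow needs single-configuration signed flows")
  if (!node %in% nodes(net)) stop("unknown node: ", node)
  if (node %in% c(flowTable@source, flowTable@target))
    return(flowTable@injectedCurrent)
  ed <- flowTable@edges
  inc <- abs(ed$flow[ed$u == node | ed$v == node])
  if (length(flowTable@groundFlows))
    inc <- c(inc, abs(flowTable@groundFlows[node]))
  0.5 * sum(inc)
}

## Voltage columns grounded at one reference node per component: column j is
## the potential vector of injecting at node j and grounding the reference;
## differences of two columns of the same component give the two-point solve.
.groundedInverse <- function(net) {
  n <- numNodes(net)
  L <- as.matrix(.laplacian(net))
  comp <- unname(.componentsOf(net))
  G <- matrix(0, n, n)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2) next
    ref <- idx[length(idx)]
    red <- setdiff(idx, ref)
    G[red, red] <- solve(L[red, red, drop = FALSE])
  }
  G
}

## Accumulated absolute edge flows T over all within-component unordered
## source-target pairs of the undirected circuit, plus the pair count.
.accumulateUndirected <- function(net, injectedCurrent = 1) {
  n <- numNodes(net)
  ei <- .edgeIndices(net)
  G <- .groundedInverse(net)
  comp <- unname(.componentsOf(net))
  Tacc <- numeric(length(ei$u))
  ## per-edge response to injecting at each node (grounded per component)
  Mdiff <- (G[ei$u, , drop = FALSE] - G[ei$v, , drop = FALSE]) * ei$c
  pairs <- 0L
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    nc <- length(idx)
    if (nc < 2) next
    pairs <- pairs + as.integer(nc * (nc - 1) / 2)
    for (k in seq_len(nc - 1)) {
      sCol <- idx[k]; tCols <- idx[(k + 1):nc]
      d <- abs(Mdiff[, sCol] - Mdiff[, tCols, drop = FALSE])
      Tacc <- Tacc + rowSums(d)
    }
  }
  list(T = Tacc * injectedCurrent, pairCount = pairs, comp = comp)
}

#' Current-flow centrality C (undirected)
#'
#' For every unordered source-target pair a unit current is driven through
#' the resistor network; the current passing through each node (half the
#' absolute incident flow, with the two endpoints fixed at the injected
#' current) is averaged over all M = N(N-1)/2 pairs. On disconnected input
#' the average runs over the within-component pairs of each component.
#'
#' @param net An undirected \linkS4class{ConductanceNetwork} with at least
#'   two nodes.
#' @param injectedCurrent Current injected per configuration.
#' @return A \linkS4class{NodeScoreTable} with scheme \code{"C_undirected"}.
#' @examples
#' currentFlowCentrality(loadFixture("twogroup13"))
#' @export
currentFlowCentrality <- function(net, injectedCurrent = 1) {
  stopifnot(is(net, "ConductanceNetwork"))
  if (isDirected(net)) stop("use directedCurrentFlowCentrality for directed networks")
  if (numNodes(net) < 2) stop("current-flow centrality needs at least two nodes")
  acc <- .accumulateUndirected(net, injectedCurrent)
  .centralityFromAccumulated(net, acc, injectedCurrent)
}

## C from accumulated flows: a node's half-sum of incident accumulated flows
## equals its summed throughflow over all pairs, except that in the (nc - 1)
## configurations where the node is an endpoint the natural half-sum is
## injected/2 (the endpoint is the potential extremum, so all its incident
## currents point one way) while the endpoint value is fixed at the full
## injection; the difference is added back.
.centralityFromAccumulated <- function(net, acc, injectedCurrent = 1) {
  n <- numNodes(net)
  inc <- .incidenceList(net)
  compSize <- table(acc$comp)[as.character(acc$comp)]
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nc <- as.integer(compSize[i])
    if (nc < 2) { scores[i] <- 0; next }
    M <- nc * (nc - 1) / 2
    scores[i] <- (0.5 * sum(acc$T[inc[[i]]]) +
                  (nc - 1) / 2 * injectedCurrent) / M
  }
  names(scores) <- nodes(net)
  new("NodeScoreTable", scores = scores, scheme = "C_undirected",
      pairCount = acc$pairCount)
}

## One full directed sweep: every node as source against the universal
## ground. Returns per-node C, merged accumulated pair flows, accumulated
## ground flows.
.directedSweep <- function(net, groundConductance = 1, tol = 1e-10,
                           maxIter = 1e5, damping = 0.5, injectedCurrent = 1,
                           method = "direct") {
  nd <- nodes(net)
  n <- length(nd)
  ei <- .edgeIndices(net)
  inc <- .incidenceList(net)
  Tacc <- numeric(length(ei$u))
  groundT <- stats::setNames(numeric(n), nd)
  thr <- stats::setNames(numeric(n), nd)
  for (s in nd) {
    pf <- tryCatch(
      solveDirected(net, s, groundConductance = groundConductance, tol = tol,
                    maxIter = maxIter, damping = damping,
                    injectedCurrent = injectedCurrent, method = method),
      error = function(e) stop("directed solve failed for source ", s, ": ",
                               conditionMessage(e), call. = FALSE))
    V <- unname(pf@voltages)
    f <- pmax(0, ei$c * (V[ei$u] - V[ei$v]))
    gf <- groundConductance * V
    Tacc <- Tacc + f
    groundT <- groundT + gf
    si <- match(s, nd)
    for (i in seq_len(n)) {
      thr[i] <- thr[i] + if (i == si) injectedCurrent
                         else 0.5 * (sum(f[inc[[i]]]) + gf[i])
    }
  }
  ## merge opposite arcs into one undirected entry by adding their flows
  key <- paste(pmin(ei$u, ei$v), pmax(ei$u, ei$v), sep = "\r")
  merged <- tapply(Tacc, key, sum)
  ku <- as.integer(sub("\r.*", "", names(merged)))
  kv <- as.integer(sub(".*\r", "", names(merged)))
  ord <- order(ku, kv)
  mergedEdges <- data.frame(u = nd[ku[ord]], v = nd[kv[ord]],
                            flow = as.numeric(merged)[ord],
                            stringsAsFactors = FALSE)
  list(C = thr / n, mergedEdges = mergedEdges, groundT = groundT,
       pairCount = n)
}

#' Current-flow centrality C (directed)
#'
#' Each node in turn acts as the source of a unit current against the
#' universal ground of the diode circuit; a node's throughflow (half the
#' absolute flow on its incident arcs plus its ground branch, the source
#' fixed at the injected current) is averaged over all N source
#' configurations.
#'
#' @param net A directed \linkS4class{ConductanceNetwork}.
#' @param groundConductance Conductance of each node's ground branch.
#' @param tol,maxIter,damping,method Passed to \code{\link{solveDirected}}.
#' @param injectedCurrent Current injected per configuration.
#' @return A \linkS4class{NodeScoreTable} with scheme \code{"C_directed"}.
#' @export
directedCurrentFlowCentrality <- function(net, groundConductance = 1,
                                          tol = 1e-10, maxIter = 1e5,
                                          damping = 0.5, injectedCurrent = 1,
                                          method = "direct") {
  stopifnot(is(net, "ConductanceNetwork"))
  if (!isDirected(net)) stop("network is undirected; use currentFlowCentrality")
  sw <- .directedSweep(net, groundConductance, tol, maxIter, damping,
                       injectedCurrent, method)
  new("NodeScoreTable", scores = sw$C, scheme = "C_directed",
      pairCount = sw$pairCount)
}

#' Accumulated absolute edge flows T
#'
#' Sums the absolute current carried by each edge over the full
#' configuration sweep: all unordered source-target pairs for an undirected
#' network, or all sources against the universal ground for a directed one.
#' In the directed case each pair of opposite arcs is merged into a single
#' undirected entry by adding the two accumulated currents, and the
#' accumulated ground-branch currents are reported in \code{groundFlows}.
#'
#' @param net A \linkS4class{ConductanceNetwork}.
#' @param groundConductance,tol,maxIter,damping,method Directed-solver
#'   settings (ignored for undirected input).
#' @param injectedCurrent Current injected per configuration.
#' @return An \linkS4class{EdgeFlowTable} in \code{accumulated_absolute}
#'   mode.
#' @export
accumulateEdgeFlows <- function(net, groundConductance = 1, tol = 1e-10,
                                maxIter = 1e5, damping = 0.5,
                                injectedCurrent = 1, method = "direct") {
  stopifnot(is(net, "ConductanceNetwork"))
  if (!isDirected(net)) {
    acc <- .accumulateUndirected(net, injectedCurrent)
    ed <- data.frame(u = net@edges$u, v = net@edges$v, flow = acc$T,
                     stringsAsFactors = FALSE)
    return(new("EdgeFlowTable", edges = ed, mode = "accumulated_absolute",
               source = NA_character_, target = NA_character_,
               injectedCurrent = injectedCurrent, groundFlows = numeric(0),
               pairCount = acc$pairCount))
  }
  sw <- .directedSweep(net, groundConductance, tol, maxIter, damping,
                       injectedCurrent, method)
  new("EdgeFlowTable", edges = sw$mergedEdges, mode = "accumulated_absolute",
      source = NA_character_, target = NA_character_,
      injectedCurrent = injectedCurrent, groundFlows = sw$groundT,
      pairCount = sw$pairCount)
}

#' Shortest-path betweenness centrality (baseline)
#'
#' The standard comparison index: the fraction of shortest paths passing
#' through each node, ties split evenly, normalized by (N-1)(N-2)/2 for
#' undirected networks (and (N-1)(N-2) for directed ones). Paths are
#' topological: conductances are not interpreted as distances.
#'
#' @param net A \linkS4class{ConductanceNetwork}.
#' @return A \linkS4class{NodeScoreTable} with scheme \code{"betweenness"}.
#' @examples
#' scores(shortestPathBetweenness(loadFixture("twogroup13")))["7"]  # 0
#' @export
shortestPathBetweenness <- function(net) {
  stopifnot(is(net, "ConductanceNetwork"))
  n <- numNodes(net)
  nd <- nodes(net)
  if (n < 3)
    return(new("NodeScoreTable",
               scores = stats::setNames(numeric(n), nd),
               scheme = "betweenness", pairCount = 0L))
  g <- asIgraph(net)
  b <- igraph::betweenness(g, directed = isDirected(net), weights = NA,
                           normalized = TRUE)
  new("NodeScoreTable", scores = stats::setNames(as.numeric(b[nd]), nd),
      scheme = "betweenness",
      pairCount = as.integer(if (isDirected(net)) (n - 1) * (n - 2)
                             else n * (n - 1) / 2))
}

#' @rdname scores
#' @export
setMethod("scores", "NodeScoreTable", function(x) x@scores)

#' @rdname scheme
#' @export
setMethod("scheme", "NodeScoreTable", function(x) x@scheme)

setMethod("show", "NodeScoreTable", function(object) {
  cat(sprintf("NodeScoreTable (%s) over %d configuration(s)\n",
              object@scheme, object@pairCount))
  top <- sort(object@scores, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "),
      "\n")
})

#' Write a score table as TSV
#'
#' Columns: node, score, scheme, rank (1 = highest score; ties share the
#' minimum rank).
#'
#' @param x A \linkS4class{NodeScoreTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeScores <- function(x, path) {
  stopifnot(is(x, "NodeScoreTable"))
  s <- x@scores
  d <- data.frame(node = names(s), score = unname(s), scheme = x@scheme,
                  rank = rank(-signif(s, 12), ties.method = "min"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
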