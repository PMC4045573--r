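#' Sentinel label for the universal ground
#'
#' In the directed circuit every node is attached to a universal sink held at
#' zero potential. The sink is not a network node; wherever a target label is
#' expected, \code{GROUND} denotes it.
#' @export
GROUND <- "GROUND"

#' ConductanceNetwork: a labeled resistor (or diode) network
#'
#' The central container: an ordered set of node labels, an edge table with a
#' positive conductance per edge, and a directedness flag. Undirected edges
#' are stored once, with endpoints in node-order; parallel edges have been
#' merged by summing conductances (resistors in parallel). Self-loops are
#' disallowed.
#'
#' @slot nodes Character vector of unique node labels.
#' @slot edges data.frame with columns \code{u}, \code{v} (character) and
#'   \code{conductance} (positive numeric, dimensionless).
#' @slot directed Logical scalar; \code{TRUE} means each row is an arc u -> v.
#'
#' @seealso \code{\link{conductanceNetwork}}, \code{\link{readNetwork}}
#' @export
setClass("ConductanceNetwork",
  representation(nodes = "character", edges = "data.frame",
                 directed = "logical"))

setValidity("ConductanceNetwork", function(object) {
  msgs <- character(0)
  nd <- object@nodes
  ed <- object@edges
  if (anyDuplicated(nd)) msgs <- c(msgs, "node labels must be unique")
  if (!identical(length(object@directed), 1L) || is.na(object@directed))
    msgs <- c(msgs, "'directed' must be TRUE or FALSE")
  if (!all(c("u", "v", "conductance") %in% names(ed)))
    msgs <- c(msgs, "edge table needs columns u, v, conductance")
  else {
    if (!all(ed$u %in% nd) || !all(ed$v %in% nd))
      msgs <- c(msgs, "edge endpoints must be network nodes")
    if (any(ed$u == ed$v)) msgs <- c(msgs, "self-loops are not allowed")
    if (!is.numeric(ed$conductance) || any(!is.finite(ed$conductance)) ||
        any(ed$conductance <= 0))
      msgs <- c(msgs, "conductances must be finite and > 0")
    key <- if (isTRUE(object@directed)) paste(ed$u, ed$v, sep = "\r")
           else paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges present (parallel edges must be merged)")
    if (!isTRUE(object@directed) && nrow(ed) > 0) {
      iu <- match(ed$u, nd); iv <- match(ed$v, nd)
      if (any(iu > iv))
        msgs <- c(msgs, "undirected edges must be stored in node order")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PotentialField: node voltages for one circuit configuration
#'
#' The solution of Kirchhoff's equations for one source-target (or
#' source-ground) configuration. Voltages are reported with the target (or
#' ground) at zero.
#'
#' @slot voltages Named numeric vector, one entry per network node (volts,
#'   arbitrary scale).
#' @slot source Source node label.
#' @slot target Target node label, or \code{\link{GROUND}}.
#' @slot injectedCurrent Positive numeric; current injected at the source
#'   (amperes, default 1).
#' @slot groundConductance Conductance of each node's ground branch in the
#'   directed circuit; \code{NA} for undirected solves.
#' @slot iterations Number of solver iterations (\code{NA} for the direct
#'   linear solve).
#' @slot residual Maximum absolute Kirchhoff residual over the checked nodes.
#'
#' @seealso \code{\link{solveUndirected}}, \code{\link{solveDirected}}
#' @export
setClass("PotentialField",
  representation(voltages = "numeric", source = "character",
                 target = "character", injectedCurrent = "numeric",
                 groundConductance = "numeric", iterations = "integer",
                 residual = "numeric"))

setValidity("PotentialField", function(object) {
  msgs <- character(0)
  if (is.null(names(object@voltages)) || anyDuplicated(names(object@voltages)))
    msgs <- c(msgs, "voltages must be uniquely named by node")
  if (any(!is.finite(object@voltages))) msgs <- c(msgs, "non-finite voltage")
  if (!(object@injectedCurrent > 0)) msgs <- c(msgs, "injectedCurrent must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' EdgeFlowTable: per-edge currents
#'
#' Either the signed currents of a single source-target configuration
#' (antisymmetric: the stored value is the current from \code{u} to \code{v})
#' or the accumulated absolute currents T summed over the full configuration
#' sweep. In directed networks a pair of opposite arcs is merged into one
#' undirected entry of the accumulated table by adding the two currents; the
#' accumulated ground-branch currents are kept separately per node.
#'
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{flow}.
#' @slot mode \code{"signed_single_pair"} or \code{"accumulated_absolute"}.
#' @slot source,target Configuration labels for the single-pair mode
#'   (\code{NA} when accumulated).
#' @slot injectedCurrent Injected current of the configuration(s).
#' @slot groundFlows Named numeric vector of ground-branch currents
#'   (empty for undirected circuits).
#' @slot pairCount Number of configurations accumulated (1 for single pair).
#' @export
setClass("EdgeFlowTable",
  representation(edges = "data.frame", mode = "character",
                 source = "character", target = "character",
                 injectedCurrent = "numeric", groundFlows = "numeric",
                 pairCount = "integer"))

setValidity("EdgeFlowTable", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("signed_single_pair", "accumulated_absolute"))
    msgs <- c(msgs, "unknown mode")
  if (!all(c("u", "v", "flow") %in% names(object@edges)))
    msgs <- c(msgs, "edge table needs columns u, v, flow")
  else if (object@mode == "accumulated_absolute" &&
           any(object@edges$flow < -1e-12))
    msgs <- c(msgs, "accumulated flows must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' NodeScoreTable: per-node scalar scores
#'
#' @slot scores Named numeric vector, one non-negative finite score per node.
#' @slot scheme One of \code{"C_undirected"}, \code{"C_directed"},
#'   \code{"D_index"}, \code{"betweenness"}.
#' @slot pairCount Number of source-target configurations averaged over
#'   (M for undirected C, N for directed C).
#' @export
setClass("NodeScoreTable",
  representation(scores = "numeric", scheme = "character",
                 pairCount = "integer"))

setValidity("NodeScoreTable", function(object) {
  msgs <- character(0)
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    msgs <- c(msgs, "scores must be uniquely named by node")
  if (any(!is.finite(object@scores)) || any(object@scores < 0))
    msgs <- c(msgs, "scores must be finite and >= 0")
  if (!object@scheme %in% c("C_undirected", "C_directed", "D_index",
                            "betweenness"))
    msgs <- c(msgs, "unknown scheme")
  if (length(msgs)) msgs else TRUE
})

#' ImbalanceResult: the flow-imbalance index D
#'
#' For each node, the raw index is the maximum minus the median of the
#' accumulated absolute flows on its incident edges; the normalized index
#' divides by the global maximum raw value (all zeros if every raw value is
#' zero). Nodes of degree 0 or 1 have index 0.
#'
#' @slot raw Named numeric vector, >= 0.
#' @slot normalized Named numeric vector in [0, 1].
#' @export
setClass("ImbalanceResult",
  representation(raw = "numeric", normalized = "numeric"))

setValidity("ImbalanceResult", function(object) {
  msgs <- character(0)
  if (!identical(names(object@raw), names(object@normalized)))
    msgs <- c(msgs, "raw and normalized must cover the same nodes")
  if (any(object@raw < 0)) msgs <- c(msgs, "raw imbalance must be >= 0")
  if (any(object@normalized < -1e-12 | object@normalized > 1 + 1e-12))
    msgs <- c(msgs, "normalized imbalance must lie in [0, 1]")
  mx <- if (length(object@raw)) max(object@raw) else 0
  if (mx > 0 && abs(max(object@normalized) - 1) > 1e-9)
    msgs <- c(msgs, "some node must attain normalized imbalance 1")
  if (length(msgs)) msgs else TRUE
})

#' KeyNodeReport: full result of the key-node analysis
#'
#' @slot thresholdC Centrality value of the last selected node (the empirical
#'   top-q cut); \code{NA} when no node is distinguishable.
#' @slot q Selection quantile (fraction of nodes taken as key nodes).
#' @slot dThreshold Normalized-imbalance threshold separating bridging from
#'   overlapping key nodes.
#' @slot keyNodes Key node labels ordered by decreasing centrality.
#' @slot overlapping,bridging Disjoint partition of \code{keyNodes}.
#' @slot centrality The C \linkS4class{NodeScoreTable}.
#' @slot imbalance The \linkS4class{ImbalanceResult}.
#' @slot directed Whether the directed circuit mapping was used.
#' @export
setClass("KeyNodeReport",
  representation(thresholdC = "numeric", q = "numeric", dThreshold = "numeric",
                 keyNodes = "character", overlapping = "character",
                 bridging = "character", centrality = "NodeScoreTable",
                 imbalance = "ImbalanceResult", directed = "logical"))

setValidity("KeyNodeReport", function(object) {
  msgs <- character(0)
  if (!setequal(c(object@overlapping, object@bridging), object@keyNodes) ||
      length(intersect(object@overlapping, object@bridging)))
    msgs <- c(msgs, "overlapping and bridging must partition the key nodes")
  if (!is.na(object@thresholdC) &&
      any(object@centrality@scores[object@keyNodes] <
          object@thresholdC - 1e-12))
    msgs <- c(msgs, "every key node must score at least thresholdC")
  if (length(msgs)) msgs else TRUE
})

#' PlantedTruth: ground truth of a synthetic benchmark network
#'
#' @slot membership Named list mapping each node label to the integer id(s)
#'   of the communities it belongs to (overlapping nodes list several).
#' @slot overlapping Labels of planted overlapping nodes.
#' @slot bridging Labels of planted bridging nodes.
#' @export
setClass("PlantedTruth",
  representation(membership = "list", overlapping = "character",
                 bridging = "character"))
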