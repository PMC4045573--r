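#' @import methods
NULL

#' Node labels of a network
#'
#' @param x A \linkS4class{ConductanceNetwork}.
#' @return Character vector of node labels, in storage order.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Number of nodes
#' @param x A \linkS4class{ConductanceNetwork}.
#' @return Integer scalar.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges (arcs for directed networks)
#' @param x A \linkS4class{ConductanceNetwork}.
#' @return Integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge table of a network or flow table
#'
#' @param x A \linkS4class{ConductanceNetwork} or \linkS4class{EdgeFlowTable}.
#' @return A data.frame with one row per edge.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Is the network directed?
#' @param x A \linkS4class{ConductanceNetwork}.
#' @return Logical scalar.
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' Node voltages of a solved circuit configuration
#' @param x A \linkS4class{PotentialField}.
#' @return Named numeric vector of voltages.
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' Per-edge currents or accumulated absolute flows
#' @param x An \linkS4class{EdgeFlowTable}.
#' @return Named numeric vector keyed \code{"u|v"}.
#' @export
setGeneric("flows", function(x) standardGeneric("flows"))

#' Per-node scores
#' @param x A \linkS4class{NodeScoreTable} or \linkS4class{KeyNodeReport}.
#' @return Named numeric vector of scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Scoring scheme identifier
#' @param x A \linkS4class{NodeScoreTable}.
#' @return Character scalar.
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' Raw imbalance values (max minus median of incident accumulated flows)
#' @param x An \linkS4class{ImbalanceResult}.
#' @return Named numeric vector.
#' @export
setGeneric("rawImbalance", function(x) standardGeneric("rawImbalance"))

#' Imbalance values normalized by the global maximum
#' @param x An \linkS4class{ImbalanceResult} or \linkS4class{KeyNodeReport}.
#' @return Named numeric vector in [0, 1].
#' @export
setGeneric("normalizedImbalance", function(x) standardGeneric("normalizedImbalance"))

#' Selected key nodes of an analysis
#' @param x A \linkS4class{KeyNodeReport}.
#' @return Character vector of node labels, ordered by decreasing centrality.
#' @export
setGeneric("keyNodes", function(x) standardGeneric("keyNodes"))

#' Key nodes classified as overlapping
#' @param x A \linkS4class{KeyNodeReport} or \linkS4class{PlantedTruth}.
#' @return Character vector of node labels.
#' @export
setGeneric("overlappingNodes", function(x) standardGeneric("overlappingNodes"))

#' Key nodes classified as bridging
#' @param x A \linkS4class{KeyNodeReport} or \linkS4class{PlantedTruth}.
#' @return Character vector of node labels.
#' @export
setGeneric("bridgingNodes", function(x) standardGeneric("bridgingNodes"))

#' Planted community membership
#' @param x A \linkS4class{PlantedTruth}.
#' @return Named list mapping each node to its community id(s).
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' Convert to an igraph object
#'
#' @param x A \linkS4class{ConductanceNetwork}.
#' @return An \code{igraph} graph; conductances become the \code{weight}
#'   edge attribute.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
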