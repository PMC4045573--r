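#' Construct a ConductanceNetwork
#'
#' Builds the validated network container from an edge table. Missing
#' conductances default to 1. Parallel edges (identical endpoints, same
#' orientation for directed input) are merged by summing their conductances,
#' which is exact for resistors in parallel. Undirected edges are
#' canonicalized so that \code{u} precedes \code{v} in node order.
#'
#' @param edges A data.frame or matrix whose first two columns are the edge
#'   endpoints and whose optional third column (or a column named
#'   \code{conductance} or \code{weight}) holds positive conductances.
#' @param nodes Optional character vector fixing the node set and order;
#'   endpoints not listed are appended in order of first appearance. Isolated
#'   nodes can only enter through this argument.
#' @param directed Logical; interpret rows as arcs u -> v.
#' @return A \linkS4class{ConductanceNetwork}.
#' @examples
#' net <- conductanceNetwork(data.frame(u = c("a", "b"), v = c("b", "c")))
#' numNodes(net)
#' @export
conductanceNetwork <- function(edges, nodes = NULL, directed = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2)
    stop("'edges' must have at least two columns (endpoints)")
  u <- as.character(edges[[1]])
  v <- as.character(edges[[2]])
  cond <- if ("conductance" %in% names(edges)) edges[["conductance"]]
          else if ("weight" %in% names(edges)) edges[["weight"]]
          else if (ncol(edges) >= 3) edges[[3]]
          else rep(1, length(u))
  cond <- as.numeric(cond)
  cond[is.na(cond)] <- 1
  if (any(!is.finite(cond)) || any(cond <= 0))
    stop("conductances must be finite and > 0")
  if (any(u == v)) stop("self-loops are not allowed")
  allNodes <- unique(c(as.character(nodes), u, v))
  if (!directed) {
    iu <- match(u, allNodes); iv <- match(v, allNodes)
    flip <- iu > iv
    tmp <- u[flip]; u[flip] <- v[flip]; v[flip] <- tmp
  }
  key <- paste(u, v, sep = "\r")
  if (anyDuplicated(key)) {
    cond <- as.numeric(tapply(cond, key, sum)[unique(key)])
    first <- !duplicated(key)
    u <- u[first]; v <- v[first]
  }
  ord <- order(match(u, allNodes), match(v, allNodes))
  ed <- data.frame(u = u[ord], v = v[ord], conductance = cond[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  new("ConductanceNetwork", nodes = allNodes, edges = ed,
      directed = isTRUE(directed))
}

#' @rdname nodes
#' @export
setMethod("nodes", "ConductanceNetwork", function(x) x@nodes)

#' @rdname numNodes
#' @export
setMethod("numNodes", "ConductanceNetwork", function(x) length(x@nodes))

#' @rdname numEdges
#' @export
setMethod("numEdges", "ConductanceNetwork", function(x) nrow(x@edges))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "ConductanceNetwork", function(x) x@edges)

#' @rdname isDirected
#' @export
setMethod("isDirected", "ConductanceNetwork", function(x) x@directed)

setMethod("show", "ConductanceNetwork", function(object) {
  cat(sprintf("ConductanceNetwork: %d nodes, %d %s (%s)\n",
              numNodes(object), numEdges(object),
              if (object@directed) "arcs" else "edges",
              if (object@directed) "directed" else "undirected"))
  if (numNodes(object)) {
    shown <- utils::head(object@nodes, 8)
    cat("  nodes:", paste(shown, collapse = ", "),
        if (numNodes(object) > 8) "..." else "", "\n")
  }
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "ConductanceNetwork", function(x) {
  d <- x@edges
  names(d) <- c("from", "to", "weight")
  igraph::graph_from_data_frame(d, directed = x@directed,
                                vertices = data.frame(name = x@nodes))
})

## ---- internal helpers ----

## edge endpoint indices into nodes(net)
.edgeIndices <- function(net) {
  list(u = match(net@edges$u, net@nodes),
       v = match(net@edges$v, net@nodes),
       c = net@edges$conductance)
}

## weighted (conductance) Laplacian, edges taken as undirected resistors
.laplacian <- function(net, sparse = TRUE) {
  n <- numNodes(net)
  ei <- .edgeIndices(net)
  W <- Matrix::sparseMatrix(i = c(ei$u, ei$v), j = c(ei$v, ei$u),
                            x = c(ei$c, ei$c), dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  if (sparse) L else as.matrix(L)
}

## membership vector of connected components (edges taken as undirected)
.componentsOf <- function(net) {
  g <- asIgraph(net)
  igraph::components(g, mode = "weak")$membership[nodes(net)]
}

## incident edge-row indices per node index
.incidenceList <- function(net) {
  n <- numNodes(net)
  ei <- .edgeIndices(net)
  inc <- vector("list", n)
  e <- seq_along(ei$u)
  split1 <- split(e, factor(ei$u, levels = seq_len(n)))
  split2 <- split(e, factor(ei$v, levels = seq_len(n)))
  for (i in seq_len(n)) inc[[i]] <- c(split1[[i]], split2[[i]])
  inc
}
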