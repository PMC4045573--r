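#' Flow-imbalance index D
#'
#' For each node, collect the accumulated absolute flows T of its incident
#' edges and take the maximum minus the median (an even count averages the
#' two middle values). A bridging node funnels most inter-community current
#' through its single bridging edge, so one incident flow towers above the
#' median and D is large; an overlapping node shares its through-current
#' over dense connections into each community, so its incident flows are
#' balanced and D is small. Raw values are normalized by the single global
#' maximum (the method never needs a community partition); if every raw
#' value is zero the normalized values are all zero. Nodes of degree 0 or 1
#' get D = 0.
#'
#' @param net The \linkS4class{ConductanceNetwork} the flows were
#'   accumulated on.
#' @param flowTable An \linkS4class{EdgeFlowTable} in
#'   \code{accumulated_absolute} mode covering every edge of \code{net}
#'   (opposite arcs of a directed network already merged).
#' @param includeGround Count a directed node's accumulated ground-branch
#'   flow among its incident values. Default \code{FALSE}: D reflects
#'   network edges only.
#' @return An \linkS4class{ImbalanceResult}.
#' @examples
#' net <- loadFixture("twogroup13")
#' dIndex(net, accumulateEdgeFlows(net))
#' @export
dIndex <- function(net, flowTable, includeGround = FALSE) {
  stopifnot(is(net, "ConductanceNetwork"), is(flowTable, "EdgeFlowTable"))
  if (flowTable@mode != "accumulated_absolute")
    stop("dIndex needs accumulated absolute flows")
  nd <- nodes(net)
  ed <- flowTable@edges
  netKey <- unique(paste(pmin(net@edges$u, net@edges$v),
                         pmax(net@edges$u, net@edges$v), sep = "\r"))
  tabKey <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
  missing <- setdiff(netKey, tabKey)
  if (length(missing))
    stop("flow table is missing ", length(missing), " network edge(s)")
  raw <- stats::setNames(numeric(length(nd)), nd)
  byNode <- split(rep(ed$flow, 2), c(ed$u, ed$v))
  if (includeGround && length(flowTable@groundFlows)) {
    gf <- flowTable@groundFlows
    for (n1 in names(byNode)) byNode[[n1]] <- c(byNode[[n1]], gf[[n1]])
  }
  for (n1 in names(byNode)) {
    v <- byNode[[n1]]
    if (length(v) >= 2) raw[n1] <- max(v) - stats::median(v)
  }
  mx <- max(raw)
  normalized <- if (mx > 0) raw / mx else raw * 0
  new("ImbalanceResult", raw = raw, normalized = normalized)
}

#' @rdname rawImbalance
#' @export
setMethod("rawImbalance", "ImbalanceResult", function(x) x@raw)

#' @rdname normalizedImbalance
#' @export
setMethod("normalizedImbalance", "ImbalanceResult", function(x) x@normalized)

setMethod("show", "ImbalanceResult", function(object) {
  cat(sprintf("ImbalanceResult over %d nodes\n", length(object@raw)))
  top <- sort(object@normalized, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  most imbalanced:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})

#' Write an imbalance result as TSV
#'
#' Columns: node, raw_D, normalized_D.
#'
#' @param x An \linkS4class{ImbalanceResult}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeImbalance <- function(x, path) {
  stopifnot(is(x, "ImbalanceResult"))
  d <- data.frame(node = names(x@raw), raw_D = unname(x@raw),
                  normalized_D = unname(x@normalized))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
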