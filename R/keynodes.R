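#' Select key nodes by thresholding the centrality
#'
#' Key nodes are the top fraction \code{q} of nodes by current-flow
#' centrality: the threshold is the score of the rank-\code{floor(q N)} node
#' (at least one), i.e. the empirical top-q cut of the score's cumulative
#' distribution, computed by rank so the threshold is attained by an actual
#' node. Nodes tied with the last selected score are all included. If every
#' node scores identically no node is distinguishable: an empty set is
#' returned with a warning.
#'
#' @param scoreTable A \linkS4class{NodeScoreTable} with scheme
#'   \code{"C_undirected"} or \code{"C_directed"}.
#' @param q Fraction of nodes to select, in (0, 1); default 0.10.
#' @return A list with \code{thresholdC} (numeric, \code{NA} when
#'   degenerate) and \code{keyNodes} (labels by decreasing score).
#' @examples
#' sel <- selectKeyNodes(currentFlowCentrality(loadFixture("zachary")))
#' sel$keyNodes
#' @export
selectKeyNodes <- function(scoreTable, q = 0.10) {
  stopifnot(is(scoreTable, "NodeScoreTable"))
  if (!scoreTable@scheme %in% c("C_undirected", "C_directed"))
    stop("key-node selection expects a current-flow centrality table")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  s <- scoreTable@scores
  if (max(s) - min(s) <= 1e-12 * max(1, max(s))) {
    warning("all centrality scores are equal; no key node distinguishable")
    return(list(thresholdC = NA_real_, keyNodes = character(0)))
  }
  k <- max(1L, as.integer(floor(q * length(s))))
  ord <- order(s, decreasing = TRUE)
  thr <- s[ord[k]]
  ## nodes numerically tied with the last selected score are all included
  tieTol <- 1e-9 * max(1, abs(thr))
  key <- names(s)[ord][s[ord] >= thr - tieTol]
  list(thresholdC = unname(thr), keyNodes = key)
}

#' Classify key nodes into overlapping vs bridging
#'
#' The default rule thresholds the normalized imbalance index: a key node
#' with D at or above \code{dThreshold} is bridging (one dominant bridging
#' edge), otherwise overlapping (balanced incident flows). No universally
#' correct threshold exists, so the cut is a declared, configurable
#' heuristic; \code{rule = "kmeans2"} instead splits the key nodes' D values
#' into two clusters (initialized at the extremes) and calls the
#' higher-center cluster bridging.
#'
#' @param keyNodeLabels Character vector of key nodes.
#' @param imbalance The \linkS4class{ImbalanceResult} of the same network
#'   and configuration sweep.
#' @param dThreshold Cut on normalized D, default 0.5.
#' @param rule \code{"threshold"} (default) or \code{"kmeans2"}.
#' @return A list with character vectors \code{overlapping} and
#'   \code{bridging}.
#' @export
classifyKeyNodes <- function(keyNodeLabels, imbalance, dThreshold = 0.5,
                             rule = c("threshold", "kmeans2")) {
  rule <- match.arg(rule)
  stopifnot(is(imbalance, "ImbalanceResult"))
  keyNodeLabels <- as.character(keyNodeLabels)
  missing <- setdiff(keyNodeLabels, names(imbalance@normalized))
  if (length(missing))
    stop("key node(s) missing from the imbalance result: ",
         paste(missing, collapse = ", "))
  d <- imbalance@normalized[keyNodeLabels]
  if (!length(d))
    return(list(overlapping = character(0), bridging = character(0)))
  if (rule == "threshold") {
    bridging <- keyNodeLabels[d >= dThreshold]
  } else {
    if (max(d) - min(d) <= 1e-12) {
      bridging <- character(0)
    } else {
      km <- stats::kmeans(matrix(d, ncol = 1),
                          centers = matrix(c(min(d), max(d)), ncol = 1))
      bridging <- keyNodeLabels[km$cluster == which.max(km$centers)]
    }
  }
  list(overlapping = setdiff(keyNodeLabels, bridging), bridging = bridging)
}

#' Run the full key-node analysis
#'
#' Composes the whole pipeline: solve the circuit for every configuration,
#' compute the current-flow centrality C and the accumulated edge flows T,
#' derive the imbalance index D, threshold C at the top fraction \code{q},
#' and classify the selected key nodes into overlapping vs bridging. The
#' result is deterministic for a given network.
#'
#' @param net A \linkS4class{ConductanceNetwork} (undirected or directed).
#' @param q Fraction of nodes selected as key nodes.
#' @param dThreshold Normalized-D cut between overlapping and bridging.
#' @param dRule Classification rule, see \code{\link{classifyKeyNodes}}.
#' @param groundConductance Ground-branch conductance of the directed
#'   circuit.
#' @param includeGroundInD Count ground-branch flows in D (directed only).
#' @param tol,maxIter,damping,method Directed-solver settings.
#' @return A \linkS4class{KeyNodeReport}.
#' @examples
#' analyzeNetwork(loadFixture("schematic32"))
#' @export
analyzeNetwork <- function(net, q = 0.10, dThreshold = 0.5,
                           dRule = "threshold", groundConductance = 1,
                           includeGroundInD = FALSE, tol = 1e-10,
                           maxIter = 1e5, damping = 0.5, method = "direct") {
  stopifnot(is(net, "ConductanceNetwork"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("analyze [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  if (isDirected(net)) {
    sw <- stage("centrality",
                .directedSweep(net, groundConductance, tol, maxIter, damping,
                               1, method))
    ctab <- new("NodeScoreTable", scores = sw$C, scheme = "C_directed",
                pairCount = sw$pairCount)
    ftab <- new("EdgeFlowTable", edges = sw$mergedEdges,
                mode = "accumulated_absolute", source = NA_character_,
                target = NA_character_, injectedCurrent = 1,
                groundFlows = sw$groundT, pairCount = sw$pairCount)
  } else {
    acc <- stage("centrality", .accumulateUndirected(net, 1))
    ctab <- stage("centrality", .centralityFromAccumulated(net, acc, 1))
    ftab <- new("EdgeFlowTable",
                edges = data.frame(u = net@edges$u, v = net@edges$v,
                                   flow = acc$T, stringsAsFactors = FALSE),
                mode = "accumulated_absolute", source = NA_character_,
                target = NA_character_, injectedCurrent = 1,
                groundFlows = numeric(0), pairCount = acc$pairCount)
  }
  imb <- stage("imbalance", dIndex(net, ftab, includeGround = includeGroundInD))
  sel <- stage("selection", selectKeyNodes(ctab, q = q))
  cls <- stage("classification",
               classifyKeyNodes(sel$keyNodes, imb, dThreshold = dThreshold,
                                rule = dRule))
  new("KeyNodeReport", thresholdC = sel$thresholdC, q = q,
      dThreshold = dThreshold, keyNodes = sel$keyNodes,
      overlapping = cls$overlapping, bridging = cls$bridging,
      centrality = ctab, imbalance = imb, directed = isDirected(net))
}

#' @rdname keyNodes
#' @export
setMethod("keyNodes", "KeyNodeReport", function(x) x@keyNodes)

#' @rdname overlappingNodes
#' @export
setMethod("overlappingNodes", "KeyNodeReport", function(x) x@overlapping)

#' @rdname bridgingNodes
#' @export
setMethod("bridgingNodes", "KeyNodeReport", function(x) x@bridging)

#' @rdname scores
#' @export
setMethod("scores", "KeyNodeReport", function(x) x@centrality@scores)

#' @rdname normalizedImbalance
#' @export
setMethod("normalizedImbalance", "KeyNodeReport",
          function(x) x@imbalance@normalized)

setMethod("show", "KeyNodeReport", function(object) {
  cat(sprintf("KeyNodeReport (%s, q = %.2f, D cut = %.2f)\n",
              if (object@directed) "directed" else "undirected",
              object@q, object@dThreshold))
  cat(sprintf("  key nodes (%d): %s\n", length(object@keyNodes),
              paste(object@keyNodes, collapse = ", ")))
  cat("  overlapping:", paste(object@overlapping, collapse = ", "), "\n")
  cat("  bridging:   ", paste(object@bridging, collapse = ", "), "\n")
})

#' Serialize a report to a plain list
#'
#' @param report A \linkS4class{KeyNodeReport}.
#' @return A nested list mirroring the report, suitable for JSON output
#'   (\code{schema_version} 1).
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "KeyNodeReport"))
  list(schema_version = 1L,
       directed = report@directed,
       q = report@q,
       d_threshold = report@dThreshold,
       threshold_C = report@thresholdC,
       key_nodes = as.list(report@keyNodes),
       overlapping = as.list(report@overlapping),
       bridging = as.list(report@bridging),
       scores = list(
         C = as.list(report@centrality@scores),
         normalized_D = as.list(report@imbalance@normalized),
         raw_D = as.list(report@imbalance@raw)),
       pair_count = report@centrality@pairCount)
}

#' Write a report as JSON
#'
#' @param report A \linkS4class{KeyNodeReport}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
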