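#' @rdname membership
#' @export
setMethod("membership", "PlantedTruth", function(x) x@membership)

#' @rdname overlappingNodes
#' @export
setMethod("overlappingNodes", "PlantedTruth", function(x) x@overlapping)

#' @rdname bridgingNodes
#' @export
setMethod("bridgingNodes", "PlantedTruth", function(x) x@bridging)

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf(
    "PlantedTruth: %d nodes, %d communities, %d overlapping, %d bridging\n",
    length(object@membership),
    length(unique(unlist(object@membership))),
    length(object@overlapping), length(object@bridging)))
})

## fixture labeling of the 13-node toy: group 1 is 1..6, the connector is 7,
## and group 2 mirrors group 1 under this permutation
.TOY13_MIRROR <- c(`1` = 11, `2` = 10, `3` = 12, `4` = 9, `5` = 13, `6` = 8)

#' Generate the two-group toy network
#'
#' Two mirrored communities of \code{groupSize} nodes are joined by a
#' central connector plus one direct edge between the two gateway nodes.
#' Because of that direct edge the connector lies on no shortest path, so
#' its shortest-path betweenness is exactly zero even though every
#' electrical path between the groups pushes current through it --- the
#' construction that separates current-flow centrality from betweenness.
#'
#' Each group consists of a hub adjacent to every other group member, a
#' gateway adjacent to the hub and to the two ends of a path through the
#' remaining nodes. At the default \code{groupSize = 6} the generated graph
#' is exactly the bundled \code{twogroup13} fixture (group 1 is nodes 1-6
#' with gateway 6, the connector is node 7, group 2 mirrors group 1 onto
#' nodes 8-13 with gateway 8). The construction is deterministic;
#' \code{seed} is accepted for interface uniformity and unused.
#'
#' @param groupSize Nodes per group, at least 3.
#' @param seed Ignored (deterministic construction).
#' @return A list with \code{network} (\linkS4class{ConductanceNetwork}) and
#'   \code{truth} (\linkS4class{PlantedTruth}; the connector is recorded as
#'   the planted overlapping node, since it belongs to both groups with the
#'   same number of edges into each).
#' @examples
#' toy <- generateTwoGroupToy()
#' numNodes(toy$network)  # 13
#' @export
generateTwoGroupToy <- function(groupSize = 6, seed = NULL) {
  m <- as.integer(groupSize)
  if (m < 3) stop("groupSize must be at least 3")
  hub <- m - 1L; gate <- m
  inner <- setdiff(seq_len(m), c(hub, gate))   # 1 .. m-2
  k <- length(inner)
  grp <- cbind(hub, setdiff(seq_len(m), hub))  # hub adjacent to all others
  if (k >= 2) {
    pathOrder <- c(k, seq_len(k - 1))          # path ends at k and k-1
    grp <- rbind(grp, cbind(pathOrder[-k], pathOrder[-1]))
    grp <- rbind(grp, cbind(gate, c(k - 1L, k)))
  } else {
    grp <- rbind(grp, cbind(gate, inner))
  }
  mirror <- if (m == 6) .TOY13_MIRROR[as.character(seq_len(m))]
            else 2L * m + 2L - seq_len(m)
  connector <- m + 1L
  ed <- rbind(grp,
              cbind(mirror[grp[, 1]], mirror[grp[, 2]]),
              c(gate, connector), c(connector, mirror[gate]),
              c(gate, mirror[gate]))
  net <- conductanceNetwork(
    data.frame(u = as.character(ed[, 1]), v = as.character(ed[, 2]),
               stringsAsFactors = FALSE),
    nodes = as.character(sort(unique(as.integer(ed)))), directed = FALSE)
  memb <- c(stats::setNames(as.list(rep(1L, m)), as.character(seq_len(m))),
            stats::setNames(list(c(1L, 2L)), as.character(connector)),
            stats::setNames(as.list(rep(2L, m)), as.character(mirror)))
  new("PlantedTruth", membership = memb[nodes(net)],
      overlapping = as.character(connector), bridging = character(0)) ->
    truth
  list(network = net, truth = truth)
}

#' Generate a planted-community network with known connectors
#'
#' Communities are dense Erdos-Renyi blocks (within-community edge
#' probability \code{pIn}). Planted bridging nodes are ordinary community
#' members that additionally receive exactly \code{bridgingOutDegree} edges
#' to uniformly drawn members of other communities; planted overlapping
#' nodes are extra nodes wired with \code{overlapDegreePerCommunity} edges
#' into each of two randomly chosen host communities. A background
#' cross-community edge probability \code{pOut} is available; its default 0
#' reproduces the schematic regime in which the communities are connected
#' only through the planted connectors (see the vignette). Generation is
#' seeded and retried until the graph is connected.
#'
#' @param nCommunities Number of communities.
#' @param communitySizes Integer vector of community sizes (each >= 3).
#' @param pIn Within-community edge probability, in (0, 1].
#' @param pOut Background cross-community edge probability, in [0, 1),
#'   strictly less than \code{pIn}; planted bridging nodes are excluded
#'   from the background process so their cross degree is exact.
#' @param nBridging Number of planted bridging nodes.
#' @param bridgingOutDegree Cross edges per bridging node (>= 1).
#' @param nOverlapping Number of planted overlapping nodes.
#' @param overlapDegreePerCommunity Edges per host community for each
#'   overlapping node (>= 2).
#' @param seed Optional integer seed.
#' @param maxRetries Connectivity retries before giving up.
#' @return A list with \code{network} and \code{truth}.
#' @examples
#' pl <- generatePlantedNetwork(seed = 1)
#' bridgingNodes(pl$truth)
#' @export
generatePlantedNetwork <- function(nCommunities = 4,
                                   communitySizes = rep(25L, nCommunities),
                                   pIn = 0.3, pOut = 0,
                                   nBridging = 2, bridgingOutDegree = 2,
                                   nOverlapping = 1,
                                   overlapDegreePerCommunity = 4,
                                   seed = NULL, maxRetries = 20) {
  nc <- as.integer(nCommunities)
  sizes <- as.integer(communitySizes)
  if (length(sizes) != nc) stop("communitySizes must have length nCommunities")
  if (any(sizes < 3)) stop("community sizes must be at least 3")
  if (!(pIn > pOut)) stop("pIn must exceed pOut")
  if (pIn <= 0 || pIn > 1 || pOut < 0 || pOut >= 1) stop("invalid edge probabilities")
  if (nOverlapping > 0 && nc < 2) stop("overlapping nodes need >= 2 communities")
  if (bridgingOutDegree < 1) stop("bridgingOutDegree must be >= 1")
  if (nOverlapping > 0 && overlapDegreePerCommunity < 2)
    stop("overlapDegreePerCommunity must be >= 2")
  if (nOverlapping > 0 && overlapDegreePerCommunity > min(sizes))
    stop("overlapDegreePerCommunity exceeds the smallest community")
  if (nBridging > sum(sizes)) stop("more bridging nodes than members")
  if (nBridging > 0 && bridgingOutDegree > sum(sizes) - max(sizes) - nBridging)
    stop("bridgingOutDegree infeasible for these community sizes")
  if (!is.null(seed)) set.seed(seed)

  total <- sum(sizes)
  commOf <- rep(seq_len(nc), sizes)
  blocks <- split(seq_len(total), commOf)
  ## bridging nodes: first members, round-robin over communities
  bridging <- integer(0)
  for (bi in seq_len(nBridging)) {
    ci <- (bi - 1L) %% nc + 1L
    bridging <- c(bridging, blocks[[ci]][(bi - 1L) %/% nc + 1L])
  }
  for (attempt in seq_len(maxRetries)) {
    eu <- integer(0); ev <- integer(0)
    for (ci in seq_len(nc)) {
      blk <- blocks[[ci]]
      pr <- t(utils::combn(blk, 2))
      take <- stats::runif(nrow(pr)) < pIn
      eu <- c(eu, pr[take, 1]); ev <- c(ev, pr[take, 2])
    }
    if (pOut > 0) {
      for (ci in seq_len(nc - 1)) for (cj in (ci + 1):nc) {
        a <- setdiff(blocks[[ci]], bridging)
        bnodes <- setdiff(blocks[[cj]], bridging)
        pr <- expand.grid(a, bnodes)
        take <- stats::runif(nrow(pr)) < pOut
        eu <- c(eu, pr[take, 1]); ev <- c(ev, pr[take, 2])
      }
    }
    for (bn in bridging) {
      pool <- setdiff(which(commOf != commOf[bn]), bridging)
      tg <- sample(pool, bridgingOutDegree)
      eu <- c(eu, rep(bn, bridgingOutDegree)); ev <- c(ev, tg)
    }
    overlapping <- integer(0)
    overlapHosts <- vector("list", nOverlapping)
    nid <- total
    for (oi in seq_len(nOverlapping)) {
      nid <- nid + 1L
      overlapping <- c(overlapping, nid)
      hosts <- sample(seq_len(nc), 2)
      overlapHosts[[oi]] <- sort(hosts)
      for (h in hosts) {
        tg <- sample(blocks[[h]], overlapDegreePerCommunity)
        eu <- c(eu, rep(nid, overlapDegreePerCommunity)); ev <- c(ev, tg)
      }
    }
    allNodes <- as.character(seq_len(nid))
    net <- conductanceNetwork(
      data.frame(u = as.character(eu), v = as.character(ev),
                 stringsAsFactors = FALSE),
      nodes = allNodes, directed = FALSE)
    ## with no cross-edge mechanism at all the communities are legitimately
    ## disconnected components; otherwise retry until connected
    needConnected <- nBridging > 0 || nOverlapping > 0 || pOut > 0
    comp <- .componentsOf(net)
    if (!needConnected || length(unique(comp)) == 1L) {
      memb <- as.list(commOf)
      names(memb) <- as.character(seq_len(total))
      for (oi in seq_along(overlapping))
        memb[[as.character(overlapping[oi])]] <- overlapHosts[[oi]]
      truth <- new("PlantedTruth", membership = memb[allNodes],
                   overlapping = as.character(overlapping),
                   bridging = as.character(bridging))
      return(list(network = net, truth = truth))
    }
  }
  stop("could not generate a connected planted network in ", maxRetries,
       " attempts; increase pOut or the planted connector counts")
}

#' Generate an LFR-style benchmark network
#'
#' Node degrees are drawn from a truncated discrete power law with exponent
#' \code{tau1} on \code{[kMin, floor(sqrt(n))]} (the truncation keeps small
#' instances connected and realizable), community sizes from a power law
#' with exponent \code{tau2}. Each node spends a fraction \code{mu} of its
#' stubs on inter-community edges and the rest inside its community; stubs
#' are matched uniformly with rejection of self-loops and multi-edges
#' (stubs that remain unmatched after bounded retries are dropped, which
#' perturbs the realized degree sequence only slightly).
#'
#' @param n Number of nodes.
#' @param tau1 Degree exponent (> 1).
#' @param tau2 Community-size exponent (> 1 after the customary shift;
#'   values >= 1 accepted).
#' @param mu Mixing parameter in [0, 1): fraction of each node's stubs that
#'   cross community borders.
#' @param avgDegree Optional target mean degree; the lower degree cutoff is
#'   chosen to approach it. Default \code{NULL} keeps the cutoff at 2.
#' @param seed Optional integer seed.
#' @return A list with \code{network} and \code{truth} (membership only;
#'   no nodes are explicitly planted).
#' @examples
#' lfr <- generateLfrLike(n = 120, seed = 1)
#' numNodes(lfr$network)
#' @export
generateLfrLike <- function(n = 250, tau1 = 2, tau2 = 1, mu = 0.1,
                            avgDegree = NULL, seed = NULL) {
  n <- as.integer(n)
  if (n < 20) stop("n must be at least 20")
  if (tau1 <= 1) stop("tau1 must exceed 1")
  if (tau2 < 1) stop("tau2 must be at least 1")
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  kMax <- max(3L, as.integer(floor(sqrt(n))))
  kMin <- 2L
  if (!is.null(avgDegree)) {
    expected <- function(k0) {
      ks <- k0:kMax; w <- ks^(-tau1); sum(ks * w) / sum(w)
    }
    cand <- seq_len(kMax - 1L)
    kMin <- cand[which.min(abs(vapply(cand, expected, 0) - avgDegree))]
  }
  ks <- kMin:kMax
  deg <- sample(ks, n, replace = TRUE, prob = ks^(-tau1))
  if (sum(deg) %% 2 == 1) deg[which.max(deg < kMax)] <- deg[which.max(deg < kMax)] + 1L
  intDeg <- round((1 - mu) * deg)
  extDeg <- deg - intDeg

  ## community sizes: power law, each large enough to host its members
  sMin <- max(10L, max(intDeg) + 1L)
  sMax <- max(2L * sMin, n %/% 3L)
  if (sMin > n) stop("degree sequence requires communities larger than n")
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sr <- sMin:sMax
    sizes <- c(sizes, sample(sr, 1, prob = sr^(-tau2)))
  }
  excess <- sum(sizes) - n
  last <- length(sizes)
  if (sizes[last] - excess >= sMin) sizes[last] <- sizes[last] - excess
  else { sizes <- sizes[-last]; sizes[1] <- sizes[1] + (n - sum(sizes)) }

  ## assign nodes (largest internal degree first) to communities with room
  cap <- sizes
  assign <- integer(n)
  for (i in order(intDeg, decreasing = TRUE)) {
    open <- which(cap > 0 & sizes > intDeg[i])
    if (!length(open)) open <- which(cap > 0)
    pick <- if (length(open) == 1) open else sample(open, 1, prob = cap[open])
    assign[i] <- pick
    cap[pick] <- cap[pick] - 1L
  }

  matchStubs <- function(stubs, forbidSame = NULL, edgeSet = character(0)) {
    ## uniform pairing with rejection; returns 2-col matrix of node indices
    out <- matrix(integer(0), 0, 2)
    for (round in 1:10) {
      if (length(stubs) < 2) break
      stubs <- sample(stubs)
      half <- floor(length(stubs) / 2)
      a <- stubs[seq_len(half)]; b <- stubs[half + seq_len(half)]
      key <- paste(pmin(a, b), pmax(a, b))
      ok <- a != b & !duplicated(key) & !(key %in% edgeSet)
      if (!is.null(forbidSame)) ok <- ok & forbidSame[a] != forbidSame[b]
      out <- rbind(out, cbind(a[ok], b[ok]))
      edgeSet <- c(edgeSet, key[ok])
      leftover <- c(a[!ok], b[!ok], if (2 * half < length(stubs)) stubs[length(stubs)])
      stubs <- leftover
    }
    out
  }

  edges <- matrix(integer(0), 0, 2)
  seen <- character(0)
  for (ci in seq_along(sizes)) {
    members <- which(assign == ci)
    stubs <- rep(members, intDeg[members])
    em <- matchStubs(stubs, edgeSet = seen)
    edges <- rbind(edges, em)
    if (nrow(em)) seen <- c(seen, paste(pmin(em[, 1], em[, 2]),
                                        pmax(em[, 1], em[, 2])))
  }
  if (mu > 0) {
    stubs <- rep(seq_len(n), extDeg)
    em <- matchStubs(stubs, forbidSame = assign, edgeSet = seen)
    edges <- rbind(edges, em)
  }
  nodesChr <- as.character(seq_len(n))
  net <- conductanceNetwork(
    data.frame(u = nodesChr[edges[, 1]], v = nodesChr[edges[, 2]],
               stringsAsFactors = FALSE),
    nodes = nodesChr, directed = FALSE)
  truth <- new("PlantedTruth",
               membership = stats::setNames(as.list(assign), nodesChr),
               overlapping = character(0), bridging = character(0))
  list(network = net, truth = truth)
}
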