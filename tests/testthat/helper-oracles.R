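# Independent oracles, kept deliberately naive and free of the package's
# solver code paths: dense pseudoinverse solves (MASS::ginv), explicit pair
# loops, BFS path enumeration, and exhaustive diode-state enumeration.

mkNet <- function(u, v, conductance = 1, directed = FALSE, nodes = NULL) {
  conductanceNetwork(data.frame(u = as.character(u), v = as.character(v),
                                conductance = conductance,
                                stringsAsFactors = FALSE),
                     nodes = nodes, directed = directed)
}

# dense conductance Laplacian by explicit loop
denseLaplacian <- function(net) {
  nd <- nodes(net)
  n <- length(nd)
  L <- matrix(0, n, n, dimnames = list(nd, nd))
  ed <- edgeTable(net)
  for (r in seq_len(nrow(ed))) {
    i <- ed$u[r]; j <- ed$v[r]; c <- ed$conductance[r]
    L[i, j] <- L[i, j] - c; L[j, i] <- L[j, i] - c
    L[i, i] <- L[i, i] + c; L[j, j] <- L[j, j] + c
  }
  L
}

# potentials of the undirected circuit via the Moore-Penrose pseudoinverse
oraclePotentials <- function(net, s, t, inj = 1) {
  G <- MASS::ginv(denseLaplacian(net))
  nd <- nodes(net)
  V <- inj * (G[, match(s, nd)] - G[, match(t, nd)])
  names(V) <- nd
  V - V[t]
}

# signed edge currents from a voltage vector (incidence times voltages)
oracleEdgeFlows <- function(net, V) {
  ed <- edgeTable(net)
  ed$conductance * (V[ed$u] - V[ed$v])
}

# current-flow centrality by explicit loop over all unordered pairs;
# endpoints contribute the injected current
oracleCFC <- function(net, inj = 1) {
  nd <- nodes(net)
  n <- length(nd)
  G <- MASS::ginv(denseLaplacian(net))
  ed <- edgeTable(net)
  scores <- stats::setNames(numeric(n), nd)
  M <- n * (n - 1) / 2
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    V <- inj * (G[, a] - G[, b]); names(V) <- nd
    f <- abs(ed$conductance * (V[ed$u] - V[ed$v]))
    for (i in seq_len(n)) {
      if (i == a || i == b) scores[i] <- scores[i] + inj
      else {
        inc <- ed$u == nd[i] | ed$v == nd[i]
        scores[i] <- scores[i] + 0.5 * sum(f[inc])
      }
    }
  }
  scores / M
}

# betweenness by BFS enumeration of every shortest path, even splitting
oracleBetweenness <- function(net) {
  nd <- nodes(net)
  n <- length(nd)
  adj <- lapply(nd, function(x) {
    ed <- edgeTable(net)
    c(ed$v[ed$u == x], ed$u[ed$v == x])
  })
  names(adj) <- nd
  score <- stats::setNames(numeric(n), nd)
  allPaths <- function(preds, s, x) {
    if (x == s) return(list(s))
    out <- list()
    for (p in preds[[x]])
      for (pp in allPaths(preds, s, p)) out <- c(out, list(c(pp, x)))
    out
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    s <- nd[a]; t <- nd[b]
    dist <- stats::setNames(rep(Inf, n), nd); dist[s] <- 0
    preds <- stats::setNames(vector("list", n), nd)
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (x in frontier) for (y in adj[[x]]) {
        if (dist[y] > dist[x] + 1) {
          dist[y] <- dist[x] + 1; preds[[y]] <- x; nxt <- c(nxt, y)
        } else if (dist[y] == dist[x] + 1 && !(x %in% preds[[y]])) {
          preds[[y]] <- c(preds[[y]], x)
        }
      }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) next
    paths <- allPaths(preds, s, t)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      score[interior] <- score[interior] + 1 / length(paths)
    }
  }
  if (n < 3) return(score)
  score / ((n - 1) * (n - 2) / 2)
}

# directed diode circuit by exhaustive enumeration of on/off states
oracleDirectedPotentials <- function(net, source, g = 1, inj = 1) {
  nd <- nodes(net)
  n <- length(nd)
  ed <- edgeTable(net)
  E <- nrow(ed)
  stopifnot(E <= 12)
  iu <- match(ed$u, nd); iv <- match(ed$v, nd)
  b <- numeric(n); b[match(source, nd)] <- inj
  for (state in 0:(2^E - 1)) {
    active <- as.logical(bitwAnd(state, 2^(seq_len(E) - 1)))
    A <- diag(g, n)
    for (r in which(active)) {
      c <- ed$conductance[r]
      A[iu[r], iu[r]] <- A[iu[r], iu[r]] + c
      A[iv[r], iv[r]] <- A[iv[r], iv[r]] + c
      A[iu[r], iv[r]] <- A[iu[r], iv[r]] - c
      A[iv[r], iu[r]] <- A[iv[r], iu[r]] - c
    }
    V <- solve(A, b)
    okOn <- all(V[iu[active]] >= V[iv[active]] - 1e-9)
    okOff <- all(V[iu[!active]] <= V[iv[!active]] + 1e-9)
    if (okOn && okOff) { names(V) <- nd; return(V) }
  }
  stop("no consistent diode state found")
}

# seeded random connected undirected graph on n nodes
randomConnectedNet <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- t(utils::combn(n, 2))
    take <- stats::runif(nrow(pairs)) < p
    if (sum(take) < n - 1) next
    net <- mkNet(pairs[take, 1], pairs[take, 2],
                 nodes = as.character(seq_len(n)))
    comp <- igraph::components(asIgraph(net))$no
    if (comp == 1) return(net)
  }
}

# seeded random directed graph (arcs oriented randomly, possibly cyclic)
randomDirectedNet <- function(n, nArcs, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- t(utils::combn(n, 2))
    pick <- sample(nrow(pairs), min(nArcs, nrow(pairs)))
    flip <- stats::runif(length(pick)) < 0.5
    u <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
    v <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
    net <- mkNet(u, v, directed = TRUE, nodes = as.character(seq_len(n)))
    if (numEdges(net) >= 1) return(net)
  }
}

# maximum-likelihood exponent of a truncated discrete power law
oraclePowerLawExponent <- function(k, kMin = min(k), kMax = max(k)) {
  negll <- function(alpha) {
    ks <- kMin:kMax
    alpha * sum(log(k)) + length(k) * log(sum(ks^(-alpha)))
  }
  stats::optimize(negll, c(1.05, 6))$minimum
}
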