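#' Solve the undirected resistor circuit for one source-target pair
#'
#' A unit current (by default) is injected at \code{source} and removed at
#' \code{target}; every edge is a resistor with its stored conductance.
#' Kirchhoff's current law at each node yields a linear system in the node
#' voltages, solved either directly (the target is grounded and the reduced
#' conductance-Laplacian system is solved sparsely) or by Jacobi iteration,
#' where each node's voltage is repeatedly replaced by the
#' conductance-weighted average of its neighbours' voltages plus the local
#' injection, until the largest voltage change drops below \code{tol}.
#'
#' @param net An undirected \linkS4class{ConductanceNetwork}.
#' @param source,target Distinct node labels in the same connected component.
#' @param method \code{"direct"} (default) or \code{"jacobi"}.
#' @param tol Convergence / residual tolerance (relative to the injected
#'   current).
#' @param maxIter Iteration cap for the Jacobi method.
#' @param injectedCurrent Current injected at the source (amperes).
#' @return A \linkS4class{PotentialField} with the target at 0 V.
#' @examples
#' net <- conductanceNetwork(data.frame(u = c("s", "m"), v = c("m", "t")))
#' voltages(solveUndirected(net, "s", "t"))
#' @export
solveUndirected <- function(net, source, target,
                            method = c("direct", "jacobi"),
                            tol = 1e-10, maxIter = 1e5, injectedCurrent = 1) {
  method <- match.arg(method)
  stopifnot(is(net, "ConductanceNetwork"))
  if (isDirected(net)) stop("solveUndirected needs an undirected network")
  nd <- nodes(net)
  if (!source %in% nd) stop("unknown source node: ", source)
  if (!target %in% nd) stop("unknown target node: ", target)
  if (identical(source, target)) stop("source and target must differ")
  comp <- .componentsOf(net)
  if (comp[source] != comp[target])
    stop("source and target lie in different connected components")
  n <- length(nd)
  s <- match(source, nd); t <- match(target, nd)
  b <- numeric(n); b[s] <- injectedCurrent; b[t] <- -injectedCurrent
  L <- .laplacian(net)
  iters <- NA_integer_
  if (method == "direct") {
    keep <- setdiff(seq_len(n), t)
    V <- numeric(n)
    V[keep] <- as.numeric(Matrix::solve(L[keep, keep, drop = FALSE], b[keep]))
  } else {
    deg <- Matrix::diag(L)
    W <- Matrix::Diagonal(n, deg) - L     # weighted adjacency
    V <- numeric(n)
    free <- setdiff(seq_len(n), t)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      Vnew <- V
      Vnew[free] <- (as.numeric(W %*% V)[free] + b[free]) / deg[free]
      delta <- max(abs(Vnew - V))
      V <- Vnew
      if (delta < tol) { iters <- it; converged <- TRUE; break }
    }
    if (!converged) {
      res <- max(abs(as.numeric(L %*% V) - b)[-c(s, t)])
      stop(sprintf(
        "Jacobi did not converge in %d iterations (interior residual %.3e)",
        as.integer(maxIter), res))
    }
  }
  r <- as.numeric(L %*% V) - b
  interior <- setdiff(seq_len(n), c(s, t))
  resid <- if (length(interior)) max(abs(r[interior])) else 0
  V <- V - V[t]                           # report target at exactly 0
  names(V) <- nd
  new("PotentialField", voltages = V, source = source, target = target,
      injectedCurrent = injectedCurrent, groundConductance = NA_real_,
      iterations = iters, residual = resid)
}

#' @rdname voltages
#' @export
setMethod("voltages", "PotentialField", function(x) x@voltages)

setMethod("show", "PotentialField", function(object) {
  cat(sprintf(
    "PotentialField: source %s -> target %s, %g A injected, residual %.2e\n",
    object@source, object@target, object@injectedCurrent, object@residual))
})

#' Edge currents of a solved configuration
#'
#' Ohm's law per edge: the current from \code{u} to \code{v} is the
#' conductance times the voltage difference. For a directed (diode)
#' solution an arc carries \code{max(0, c * (V_u - V_v))}: an ideal diode
#' conducts only in its orientation, and a tie carries zero current. The
#' ground-branch currents of a directed solution are included as
#' \code{groundFlows}.
#'
#' @param net The \linkS4class{ConductanceNetwork} that was solved.
#' @param potentials The matching \linkS4class{PotentialField}.
#' @return An \linkS4class{EdgeFlowTable} in \code{signed_single_pair} mode.
#' @export
edgeCurrents <- function(net, potentials) {
  stopifnot(is(net, "ConductanceNetwork"), is(potentials, "PotentialField"))
  V <- potentials@voltages
  if (!setequal(names(V), nodes(net)))
    stop("potentials do not cover the network's node set")
  ed <- net@edges
  dV <- V[ed$u] - V[ed$v]
  f <- ed$conductance * dV
  gf <- numeric(0)
  if (isDirected(net)) {
    f <- pmax(0, f)
    g <- potentials@groundConductance
    if (is.finite(g)) gf <- g * V[nodes(net)]
  }
  new("EdgeFlowTable",
      edges = data.frame(u = ed$u, v = ed$v, flow = unname(f),
                         stringsAsFactors = FALSE),
      mode = "signed_single_pair", source = potentials@source,
      target = potentials@target,
      injectedCurrent = potentials@injectedCurrent,
      groundFlows = gf, pairCount = 1L)
}

#' @rdname flows
#' @export
setMethod("flows", "EdgeFlowTable", function(x) {
  stats::setNames(x@edges$flow, paste(x@edges$u, x@edges$v, sep = "|"))
})

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "EdgeFlowTable", function(x) x@edges)

setMethod("show", "EdgeFlowTable", function(object) {
  cat(sprintf("EdgeFlowTable (%s): %d edges over %d configuration(s)\n",
              object@mode, nrow(object@edges), object@pairCount))
})

#' Solve the directed diode circuit for one source
#'
#' Every arc is an ideal diode in series with its conductance: it conducts
#' with that conductance when the tail voltage exceeds the head voltage and
#' blocks otherwise. Every node is additionally attached to a universal
#' ground held at 0 V through a branch of conductance
#' \code{groundConductance}. A constant current is injected at the source
#' and all of it eventually leaves through the ground branches.
#'
#' Two schemes solve the resulting piecewise-linear fixed point. The default
#' \code{"direct"} scheme alternates exact sparse solves of the linear
#' system induced by the currently conducting diode set with updates of that
#' set, and falls back to relaxation if the set cycles. The
#' \code{"relaxation"} scheme performs damped Jacobi sweeps in which each
#' node moves toward the conductance-weighted average of its conducting
#' neighbours and ground; damping is needed because diode switching makes
#' the undamped map discontinuous.
#'
#' @param net A directed \linkS4class{ConductanceNetwork}.
#' @param source Source node label.
#' @param groundConductance Positive conductance of each node's ground
#'   branch.
#' @param tol Residual tolerance relative to the injected current.
#' @param maxIter Iteration cap for the relaxation scheme.
#' @param damping Damping factor in (0, 1] for the relaxation scheme.
#' @param injectedCurrent Current injected at the source.
#' @param method \code{"direct"} (default) or \code{"relaxation"}.
#' @return A \linkS4class{PotentialField} with \code{target = GROUND}.
#' @examples
#' net <- conductanceNetwork(data.frame(u = "s", v = "t"), directed = TRUE)
#' voltages(solveDirected(net, "s"))
#' @export
solveDirected <- function(net, source, groundConductance = 1,
                          tol = 1e-10, maxIter = 1e5, damping = 0.5,
                          injectedCurrent = 1,
                          method = c("direct", "relaxation")) {
  method <- match.arg(method)
  stopifnot(is(net, "ConductanceNetwork"))
  if (!isDirected(net)) stop("solveDirected needs a directed network")
  nd <- nodes(net)
  if (GROUND %in% nd) stop("node label '", GROUND, "' is reserved")
  if (!source %in% nd) stop("unknown source node: ", source)
  if (!is.numeric(groundConductance) || groundConductance <= 0)
    stop("groundConductance must be > 0")
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  n <- length(nd)
  s <- match(source, nd)
  ei <- .edgeIndices(net)
  b <- numeric(n); b[s] <- injectedCurrent
  g <- groundConductance

  solveActive <- function(active) {
    ia <- c(ei$u[active], ei$v[active])
    ja <- c(ei$v[active], ei$u[active])
    xa <- c(ei$c[active], ei$c[active])
    W <- Matrix::sparseMatrix(i = ia, j = ja, x = xa, dims = c(n, n))
    A <- Matrix::Diagonal(n, Matrix::rowSums(W) + g) - W
    as.numeric(Matrix::solve(A, b))
  }
  residualOf <- function(V) {
    f <- pmax(0, ei$c * (V[ei$u] - V[ei$v]))
    net_out <- g * V - b
    if (length(f))
      net_out <- net_out + as.numeric(
        tapply(c(f, -f), factor(c(ei$u, ei$v), levels = seq_len(n)), sum,
               default = 0))
    max(abs(net_out))
  }

  V <- NULL; iters <- NA_integer_
  if (method == "direct") {
    active <- rep(TRUE, length(ei$u))
    seen <- character(0)
    ok <- FALSE
    for (it in seq_len(100L)) {
      V <- solveActive(active)
      newActive <- V[ei$u] > V[ei$v]
      if (identical(newActive, active)) { ok <- TRUE; iters <- it; break }
      sig <- paste(as.integer(newActive), collapse = "")
      if (sig %in% seen) break            # cycling: defer to relaxation
      seen <- c(seen, sig)
      active <- newActive
    }
    if (!ok || residualOf(V) > tol * injectedCurrent) {
      V <- NULL                           # fall through to relaxation
    }
  }
  if (is.null(V)) {
    V <- numeric(n)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      condIn <- ei$c * (V[ei$u] > V[ei$v])      # conducting arcs only
      num <- b; den <- rep(g, n)
      if (length(condIn)) {
        contrib <- c(condIn * V[ei$u], condIn * V[ei$v])
        where <- c(ei$v, ei$u)
        num <- num + as.numeric(tapply(contrib, factor(where, seq_len(n)), sum,
                                       default = 0))
        den <- den + as.numeric(tapply(c(condIn, condIn),
                                       factor(where, seq_len(n)), sum,
                                       default = 0))
      }
      Vnew <- (1 - damping) * V + damping * num / den
      delta <- max(abs(Vnew - V))
      V <- Vnew
      if (delta < tol && residualOf(V) <= tol * injectedCurrent) {
        iters <- it; converged <- TRUE; break
      }
    }
    if (!converged)
      stop(sprintf(
        "directed relaxation did not converge for source %s (residual %.3e)",
        source, residualOf(V)))
  }
  resid <- residualOf(V)
  names(V) <- nd
  new("PotentialField", voltages = V, source = source, target = GROUND,
      injectedCurrent = injectedCurrent, groundConductance = g,
      iterations = iters, residual = resid)
}
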