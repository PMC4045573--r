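#' Read a network from a file
#'
#' Supported formats: a plain edge list (one \code{"u v [conductance]"} per
#' line, separated by whitespace or commas, \code{#} comments and blank lines
#' ignored), GML, and GraphML. Missing conductances default to 1; parallel
#' edges are merged by summing conductances. For GML/GraphML the
#' directedness recorded in the file wins and \code{directed} is ignored.
#'
#' @param path Path to the file.
#' @param format One of \code{"edgelist"}, \code{"gml"}, \code{"graphml"}.
#' @param directed Logical; orientation of edge-list rows.
#' @return A \linkS4class{ConductanceNetwork}.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c 2"), f)
#' readNetwork(f)
#' @export
readNetwork <- function(path, format = c("edgelist", "gml", "graphml"),
                        directed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edgelist") {
    ln <- readLines(path, warn = FALSE)
    ln <- sub("#.*$", "", ln)
    keep <- which(trimws(ln) != "")
    if (!length(keep)) stop("no edges in ", path)
    parts <- strsplit(trimws(ln[keep]), "[,\t ]+")
    nf <- lengths(parts)
    bad <- which(nf < 2 | nf > 3)
    if (length(bad))
      stop(sprintf("malformed edge-list line %d in %s: '%s'",
                   keep[bad[1]], path, trimws(ln[keep[bad[1]]])))
    u <- vapply(parts, `[`, "", 1)
    v <- vapply(parts, `[`, "", 2)
    cond <- rep(1, length(parts))
    has3 <- nf == 3
    if (any(has3)) {
      cv <- suppressWarnings(as.numeric(vapply(parts[has3], `[`, "", 3)))
      if (anyNA(cv)) {
        bad <- keep[has3][which(is.na(cv))[1]]
        stop(sprintf("non-numeric conductance on line %d in %s", bad, path))
      }
      cond[has3] <- cv
    }
    return(conductanceNetwork(data.frame(u = u, v = v, conductance = cond,
                                         stringsAsFactors = FALSE),
                              directed = directed))
  }
  g <- igraph::read_graph(path, format = format)
  .fromIgraph(g)
}

.fromIgraph <- function(g) {
  va <- igraph::vertex_attr_names(g)
  labels <- if ("name" %in% va) as.character(igraph::V(g)$name)
            else if ("label" %in% va) as.character(igraph::V(g)$label)
            else if ("id" %in% va) as.character(igraph::V(g)$id)
            else as.character(seq_len(igraph::vcount(g)))
  ends <- igraph::as_edgelist(g, names = FALSE)
  cond <- if ("weight" %in% igraph::edge_attr_names(g))
            as.numeric(igraph::E(g)$weight) else rep(1, igraph::ecount(g))
  conductanceNetwork(
    data.frame(u = labels[ends[, 1]], v = labels[ends[, 2]],
               conductance = cond, stringsAsFactors = FALSE),
    nodes = labels, directed = igraph::is_directed(g))
}

#' Write a network to a file
#'
#' The written file round-trips: \code{readNetwork()} on the output
#' reproduces the node set, edge set, conductances and directedness.
#'
#' @param net A \linkS4class{ConductanceNetwork}.
#' @param path Output path.
#' @param format One of \code{"edgelist"}, \code{"gml"}, \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "ConductanceNetwork"))
  if (format == "edgelist") {
    ed <- net@edges
    hdr <- sprintf("# %s edge list: u v conductance",
                   if (net@directed) "directed" else "undirected")
    iso <- setdiff(net@nodes, c(ed$u, ed$v))
    if (length(iso))
      warning("isolated nodes are not representable in an edge list: ",
              paste(iso, collapse = ", "))
    writeLines(c(hdr, sprintf("%s\t%s\t%s", ed$u, ed$v,
                              format(ed$conductance, digits = 17))), path)
  } else {
    igraph::write_graph(asIgraph(net), path, format = format)
  }
  invisible(path)
}

#' Load a bundled example network
#'
#' Three small undirected networks ship with the package:
#' \describe{
#'   \item{\code{zachary}}{Zachary's karate club, the classic 34-member
#'     social network (unweighted: every conductance 1).}
#'   \item{\code{schematic32}}{A synthetic 32-node network of three
#'     communities joined by one overlapping node (12, four edges into each
#'     of two communities) and two bridging hubs (16 and 24, one bridging
#'     edge each); built as a worked illustration of the method.}
#'   \item{\code{twogroup13}}{A 13-node network of two mirrored 6-node
#'     groups whose gateways (6 and 8) are joined both directly and through
#'     the central connector 7, so that the connector lies on no shortest
#'     path. The standard worked example contrasting current-flow
#'     centrality with shortest-path betweenness.}
#' }
#'
#' @param name Fixture name.
#' @return A \linkS4class{ConductanceNetwork}.
#' @examples
#' numNodes(loadFixture("zachary"))
#' @export
loadFixture <- function(name) {
  files <- c(zachary = "zachary.tsv",
             schematic32 = "schematic32_synthetic.tsv",
             twogroup13 = "twogroup13.tsv")
  if (length(name) != 1 || !name %in% names(files))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "CircuitKeys",
                      mustWork = TRUE)
  readNetwork(path, format = "edgelist", directed = FALSE)
}
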