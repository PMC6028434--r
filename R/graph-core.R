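#' Read a directed network from an edge-list or SIF file
#'
#' Accepts whitespace/TAB-separated files with two columns (`source target`),
#' three columns where the third is numeric (`source target score`), or the
#' three-column SIF dialect (`source interaction target`). Identifiers are
#' whitespace-trimmed; duplicate ordered pairs collapse to one edge.
#'
#' @param path file path.
#' @param provenance tag attached to every edge read (default `"regulatory"`).
#' @return a [DirectedNetwork-class].
#' @export
readNetwork <- function(path, provenance = "regulatory") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("malformed network line ", bad[1], " in ", path, ": '",
         lines[bad[1]], "'")
  from <- vapply(toks, `[`, character(1), 1L)
  third <- ifelse(nf >= 3L, vapply(toks, `[`, character(1), 3L), NA)
  num3 <- !is.na(suppressWarnings(as.numeric(third)))
  # SIF dialect: 3 columns with a non-numeric middle token -> col3 is target
  sif <- nf >= 3L & !num3
  to <- ifelse(sif, third, vapply(toks, `[`, character(1), 2L))
  score <- ifelse(nf >= 3L & num3, suppressWarnings(as.numeric(third)),
                  NA_real_)
  directedNetwork(from, to, provenance = provenance, score = score)
}

#' Write a network as a TSV edge list with provenance
#'
#' @param net a [DirectedNetwork-class].
#' @param path output path.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "DirectedNetwork"))
  write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Merge networks, unioning edges and provenance tags
#'
#' Extends a base network (e.g. an inferred GRN) with further edge sets such
#' as kinase-substrate and signaling interactions, giving the extended
#' gene-regulatory network (EGRN). An edge present in several inputs keeps a
#' single record whose provenance is the union of the tags.
#'
#' @param base a [DirectedNetwork-class].
#' @param extensions a list of `DirectedNetwork` objects (or a single one).
#' @return the merged [DirectedNetwork-class].
#' @export
mergeNetworks <- function(base, extensions = list()) {
  if (is(extensions, "DirectedNetwork")) extensions <- list(extensions)
  nets <- c(list(base), extensions)
  e <- do.call(rbind, lapply(nets, edgeTable))
  nd <- unlist(lapply(nets, nodeIds))
  directedNetwork(e$from, e$to, provenance = e$provenance, score = e$score,
                  nodes = nd)
}

#' Largest (weakly) connected component
#'
#' Connectivity is judged on the undirected projection. Ties on component
#' size are broken in favor of the component containing the lexicographically
#' smallest node id.
#'
#' @param net a [DirectedNetwork-class].
#' @return a [DirectedNetwork-class] restricted to the winning component.
#' @export
largestComponent <- function(net) {
  if (nNodes(net) == 0L) stop("cannot take the LCC of an empty network")
  g <- asIgraph(net)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest member id decides
    firsts <- vapply(best, function(k)
      min(igraph::V(g)$name[comp$membership == k]), character(1))
    best <- best[order(firsts)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  subsetNetwork(net, keep)
}

#' Restrict a network to a node subset
#'
#' @param net a [DirectedNetwork-class].
#' @param keep character vector of node ids to retain.
#' @return the induced sub-network.
#' @export
subsetNetwork <- function(net, keep) {
  e <- edgeTable(net)
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  directedNetwork(e$from, e$to, provenance = e$provenance, score = e$score,
                  nodes = intersect(nodeIds(net), keep))
}

#' Degree-preserving randomization by double edge swaps
#'
#' Rewires the network with repeated directed double-edge swaps
#' (igraph's `keeping_degseq`), which preserve every node's in-degree and
#' out-degree exactly while rejecting self-loops and duplicate edges.
#'
#' @param net a [DirectedNetwork-class].
#' @param nSwapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a rewired [DirectedNetwork-class] with provenance `"random"`.
#' @export
rewireNetwork <- function(net, nSwapsPerEdge = 10, seed = 1L) {
  stopifnot(nSwapsPerEdge >= 1)
  if (nEdges(net) < 2L) {
    warning("fewer than 2 edges; returning an unmodified copy")
    return(net)
  }
  g <- asIgraph(net)
  withr::local_seed(seed)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = nSwapsPerEdge * nEdges(net)))
  el <- igraph::as_edgelist(g2)
  directedNetwork(el[, 1], el[, 2], provenance = "random",
                  nodes = nodeIds(net))
}

#' Topology summary with z-scores against a randomized ensemble
#'
#' Computes, on the undirected projection: the average shortest path length
#' over connected node pairs, the average local clustering coefficient
#' (isolated and degree-1 nodes count 0), and the average neighbor count.
#' The observed path length and clustering are converted to z-scores against
#' `nRandom` degree-preserving randomizations of the directed network.
#'
#' @param net a [DirectedNetwork-class].
#' @param nRandom ensemble size (default 100).
#' @param seed integer seed for the ensemble.
#' @return a [TopologySummary-class].
#' @export
topologySummary <- function(net, nRandom = 100, seed = 1L) {
  stopifnot(nRandom >= 1)
  obs <- topologyMetrics(net)
  rnd <- vapply(seq_len(nRandom), function(k) {
    m <- topologyMetrics(rewireNetwork(net, seed = seed + k))
    c(m$aspl, m$clustering)
  }, numeric(2))
  zden <- apply(rnd, 1L, sd)
  z <- (c(obs$aspl, obs$clustering) - rowMeans(rnd)) / zden
  new("TopologySummary",
      avgShortestPath = obs$aspl,
      clusteringCoefficient = obs$clustering,
      avgNeighbors = obs$neighbors,
      zAspl = z[1], zClustering = z[2],
      nRandom = as.integer(nRandom), connected = obs$connected)
}

topologyMetrics <- function(net) {
  gu <- asIgraph(net, directed = FALSE)
  comp <- igraph::components(gu)
  list(
    aspl = igraph::mean_distance(gu, directed = FALSE, unconnected = TRUE),
    clustering = mean(igraph::transitivity(gu, type = "local",
                                           isolates = "zero")),
    neighbors = mean(igraph::degree(gu)),
    connected = comp$no == 1L)
}
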