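#' @import methods
#' @importFrom stats var sd quantile pt p.adjust fisher.test wilcox.test
#'   rnorm rbinom runif rpois lm.fit setNames ks.test cor
#' @importFrom utils read.table write.table head
NULL

#' Directed gene network with edge provenance
#'
#' Container for a simple directed graph over gene identifiers. Each ordered
#' pair of genes appears at most once; provenance tags (e.g. `"regulatory"`,
#' `"kinase"`, `"signaling"`, `"prior"`) accumulate into a comma-separated set
#' when networks are merged. An optional numeric score per edge carries
#' inference confidence.
#'
#' @slot nodes character vector of unique gene identifiers.
#' @slot edges data.frame with columns `from`, `to`, `provenance`, `score`.
#'
#' @seealso [directedNetwork()], [readNetwork()], [mergeNetworks()]
#' @export
setClass("DirectedNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("DirectedNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("from", "to", "provenance", "score") %in% names(e)))
    msgs <- c(msgs, "edges must have columns from, to, provenance, score")
  else {
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msgs <- c(msgs, "duplicated ordered edge")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msgs <- c(msgs, "edge endpoint not in nodes")
    if (any(e$from == e$to))
      msgs <- c(msgs, "self-loops are not allowed")
  }
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicated node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DirectedNetwork
#'
#' Duplicate ordered pairs are collapsed; their provenance tags are unioned
#' and the maximum score is kept. Self-loops are rejected.
#'
#' @param from,to character vectors of source and target gene ids.
#' @param provenance single tag or vector of tags per edge.
#' @param score optional numeric score per edge (`NA` allowed).
#' @param nodes optional extra isolated nodes to include.
#' @return A [DirectedNetwork-class] object.
#' @examples
#' net <- directedNetwork(c("A", "B"), c("B", "C"))
#' nNodes(net); nEdges(net)
#' @export
directedNetwork <- function(from = character(), to = character(),
                            provenance = "regulatory", score = NA_real_,
                            nodes = character()) {
  from <- trimws(as.character(from)); to <- trimws(as.character(to))
  stopifnot(length(from) == length(to))
  if (any(from == to)) {
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    provenance <- if (length(provenance) > 1) provenance[keep] else provenance
    score <- if (length(score) > 1) score[keep] else score
  }
  e <- data.frame(from = from, to = to,
                  provenance = rep_len(as.character(provenance),
                                       length(from)),
                  score = rep_len(as.numeric(score), length(from)),
                  stringsAsFactors = FALSE)
  if (nrow(e)) {
    key <- paste(e$from, e$to, sep = "\r")
    if (anyDuplicated(key)) {
      tags <- vapply(split(e$provenance, key), function(p)
        paste(sort(unique(unlist(strsplit(p, ",", fixed = TRUE)))),
              collapse = ","), character(1))
      sc <- vapply(split(e$score, key), function(s)
        if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE), numeric(1))
      first <- !duplicated(key)
      e <- e[first, , drop = FALSE]
      k <- paste(e$from, e$to, sep = "\r")
      e$provenance <- unname(tags[k]); e$score <- unname(sc[k])
    }
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }
  allnodes <- sort(unique(c(e$from, e$to, trimws(as.character(nodes)))))
  new("DirectedNetwork", nodes = allnodes, edges = e)
}

#' @describeIn DirectedNetwork-class number of nodes
#' @param object,x a `DirectedNetwork`
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname DirectedNetwork-class
#' @export
setMethod("nNodes", "DirectedNetwork", function(x) length(x@nodes))
#' @rdname DirectedNetwork-class
#' @export
setMethod("nEdges", "DirectedNetwork", function(x) nrow(x@edges))
#' @rdname DirectedNetwork-class
#' @export
setMethod("nodeIds", "DirectedNetwork", function(x) x@nodes)
#' @rdname DirectedNetwork-class
#' @export
setMethod("edgeTable", "DirectedNetwork", function(x) x@edges)

setMethod("show", "DirectedNetwork", function(object) {
  cat("DirectedNetwork with", nNodes(object), "nodes and",
      nEdges(object), "edges\n")
  tags <- sort(unique(unlist(strsplit(object@edges$provenance, ",",
                                      fixed = TRUE))))
  if (length(tags)) cat("  provenance:", paste(tags, collapse = ", "), "\n")
})

#' Convert a DirectedNetwork to an igraph object
#'
#' @param x a [DirectedNetwork-class].
#' @param directed keep edge direction (default) or project to an undirected
#'   simple graph.
#' @return an [igraph::igraph] graph whose vertex names are the gene ids.
#' @export
asIgraph <- function(x, directed = TRUE) {
  stopifnot(is(x, "DirectedNetwork"))
  g <- igraph::graph_from_data_frame(x@edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = x@nodes))
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' Per-node control centrality over one network
#'
#' Holds the integer control centrality C_c(i) of every node — the generic
#' dimension of the subspace controllable by driving node i alone — together
#' with the network size N. The normalized value c_c(i) = C_c(i)/N is derived
#' exactly, never stored.
#'
#' @slot cc named integer vector, one entry per network node, each in [1, N].
#' @slot N network node count.
#' @seealso [controlCentralityAll()]
#' @export
setClass("CcResult", representation(cc = "integer", N = "integer"))

setValidity("CcResult", function(object) {
  if (length(object@N) != 1L) return("N must be scalar")
  if (is.null(names(object@cc))) return("cc must be named by node")
  if (any(object@cc < 1L | object@cc > object@N))
    return("cc values must lie in [1, N]")
  TRUE
})

#' @export
setGeneric("ccValues", function(x) standardGeneric("ccValues"))
#' @export
setGeneric("normalizedCc", function(x) standardGeneric("normalizedCc"))

#' @rdname CcResult-class
#' @param x a `CcResult`
#' @export
setMethod("ccValues", "CcResult", function(x) x@cc)
#' @rdname CcResult-class
#' @export
setMethod("normalizedCc", "CcResult", function(x) x@cc / x@N)

setMethod("show", "CcResult", function(object) {
  cat("CcResult over", object@N, "nodes; mean Cc =",
      format(mean(object@cc), digits = 5),
      "; max Cc =", max(object@cc), "\n")
})

#' Topology diagnostics with randomized-ensemble z-scores
#'
#' Summary of the undirected projection of a network: average shortest path
#' length over connected pairs, average local clustering coefficient, average
#' neighbor count, and z-scores of the first two against an ensemble of
#' degree-preserving randomizations.
#'
#' @slot avgShortestPath mean shortest path length over reachable pairs.
#' @slot clusteringCoefficient average local clustering in [0, 1].
#' @slot avgNeighbors mean number of neighbors (undirected degree).
#' @slot zAspl,zClustering z-scores vs the randomized ensemble.
#' @slot nRandom ensemble size.
#' @slot connected whether the undirected projection was connected; when
#'   FALSE the path length is averaged over reachable pairs only.
#' @export
setClass("TopologySummary",
  representation(avgShortestPath = "numeric",
                 clusteringCoefficient = "numeric",
                 avgNeighbors = "numeric",
                 zAspl = "numeric", zClustering = "numeric",
                 nRandom = "integer", connected = "logical"))

setMethod("show", "TopologySummary", function(object) {
  cat("TopologySummary (undirected projection",
      if (!object@connected) ", disconnected: reachable pairs only", ")\n",
      sep = "")
  cat(sprintf("  <l> = %.4g (z = %.3g)\n", object@avgShortestPath,
              object@zAspl))
  cat(sprintf("  C   = %.4g (z = %.3g)\n", object@clusteringCoefficient,
              object@zClustering))
  cat(sprintf("  avg neighbors = %.4g; ensemble n = %d\n",
              object@avgNeighbors, object@nRandom))
})

#' SNP dosage matrix with genomic positions
#'
#' @slot dosages numeric matrix, SNPs in rows (rownames = SNP ids), samples in
#'   columns; values in [0, 2] (hard calls 0/1/2 or imputed dosages).
#' @slot snpPos data.frame with columns `snp`, `chr`, `pos` (1-based).
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpPos = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  if (!identical(rownames(object@dosages), object@snpPos$snp))
    return("dosage rownames must equal snpPos$snp in order")
  if (any(object@snpPos$pos < 0)) return("positions must be non-negative")
  d <- object@dosages
  if (length(d) && (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2))
    return("dosages must lie in [0, 2]")
  TRUE
})

#' @param dosages,snpPos see slots.
#' @rdname GenotypeMatrix-class
#' @export
genotypeMatrix <- function(dosages, snpPos) {
  dosages <- as.matrix(dosages)
  snpPos <- as.data.frame(snpPos)
  stopifnot(all(c("snp", "chr", "pos") %in% names(snpPos)))
  snpPos$snp <- as.character(snpPos$snp)
  snpPos$chr <- as.character(snpPos$chr)
  if (is.null(rownames(dosages))) rownames(dosages) <- snpPos$snp
  new("GenotypeMatrix", dosages = dosages,
      snpPos = snpPos[, c("snp", "chr", "pos")])
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "SNPs x",
      ncol(object@dosages), "samples on",
      length(unique(object@snpPos$chr)), "chromosome(s)\n")
})

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpPositions", "GenotypeMatrix", function(x) x@snpPos)

#' Node-weighted Steiner tree solution
#'
#' @slot terminals terminal genes present in the network.
#' @slot linkers non-terminal genes added to connect the terminals.
#' @slot edges data.frame (`from`, `to`) of the undirected solution tree(s).
#' @slot totalNodeCost summed node cost of the linkers.
#' @slot partial TRUE when the terminals span several components and a forest
#'   (one tree per component) was returned.
#' @export
setClass("SteinerSolution",
  representation(terminals = "character", linkers = "character",
                 edges = "data.frame", totalNodeCost = "numeric",
                 partial = "logical"))

setValidity("SteinerSolution", function(object) {
  if (length(intersect(object@terminals, object@linkers)))
    return("linkers and terminals must be disjoint")
  TRUE
})

setMethod("show", "SteinerSolution", function(object) {
  cat("SteinerSolution:", length(object@terminals), "terminals,",
      length(object@linkers), "linkers, cost",
      format(object@totalNodeCost), if (object@partial) "(partial forest)",
      "\n")
})
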