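#' Klein-Ravi node-weighted Steiner tree
#'
#' Connects a set of terminal genes inside an interaction network with the
#' Klein-Ravi greedy approximation of the node-weighted Steiner tree: each
#' terminal starts as its own tree, and the algorithm repeatedly picks the
#' node v and the k >= 2 trees minimizing
#' `(cost(v) + sum of node-cost shortest-path distances from v to the trees) / k`,
#' merging them along those paths, until one tree remains. Nodes already in
#' the solution cost nothing, so directly interacting terminals merge first
#' at zero cost. Degree-1 non-terminals are pruned from the final tree.
#' Ties break by node id, making the result deterministic.
#'
#' Terminals absent from the network are dropped with a warning. When the
#' terminals span several connected components, one tree per component is
#' returned and the solution is flagged partial.
#'
#' @param net a [DirectedNetwork-class] (edge direction is ignored) or an
#'   undirected igraph graph.
#' @param terminals character vector of terminal gene ids (>= 2 in network).
#' @param nodeCosts named numeric vector of node costs; unnamed default 1
#'   for every node. Terminals always cost 0.
#' @return a [SteinerSolution-class].
#' @export
kleinRaviSteiner <- function(net, terminals, nodeCosts = NULL) {
  g <- if (is(net, "DirectedNetwork")) asIgraph(net, directed = FALSE)
       else igraph::as_undirected(net, mode = "collapse")
  vn <- igraph::V(g)$name
  absent <- setdiff(terminals, vn)
  if (length(absent))
    warning(length(absent), " terminal(s) not in network, dropped: ",
            paste(head(absent, 5), collapse = ", "))
  terminals <- sort(intersect(unique(terminals), vn))
  if (length(terminals) < 2L)
    stop("need at least 2 terminals present in the network")
  cost <- setNames(rep(1, length(vn)), vn)
  if (!is.null(nodeCosts)) cost[names(nodeCosts)] <- nodeCosts
  cost[terminals] <- 0

  comp <- igraph::components(g)
  tcomp <- comp$membership[terminals]
  partial <- length(unique(tcomp)) > 1L
  allNodes <- character(); allEdges <- list()
  for (ci in sort(unique(tcomp))) {
    sub <- igraph::induced_subgraph(g, vn[comp$membership == ci])
    res <- kleinRaviComponent(sub, terminals[tcomp == ci], cost)
    allNodes <- c(allNodes, res$nodes)
    allEdges <- c(allEdges, list(res$edges))
  }
  edges <- do.call(rbind, allEdges)
  linkers <- sort(setdiff(allNodes, terminals))
  new("SteinerSolution", terminals = terminals, linkers = linkers,
      edges = edges, totalNodeCost = sum(cost[linkers]),
      partial = partial)
}

# greedy merge inside one connected component; returns solution node ids and
# a spanning tree (pruned) over them
kleinRaviComponent <- function(g, terminals, cost) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  nbrs <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                 function(v) sort(as.integer(v)))
  ec <- unname(cost[vn])
  trees <- lapply(match(sort(terminals), vn), function(i) i)
  inSolution <- logical(n)
  for (tr in trees) inSolution[tr] <- TRUE

  # Dijkstra over node costs from a multi-node source; cost of reaching u is
  # the summed cost of interior nodes plus u itself (source nodes cost 0)
  dijkstra <- function(sources, effCost) {
    d <- rep(Inf, n); pred <- rep(NA_integer_, n)
    d[sources] <- 0
    done <- logical(n)
    repeat {
      cand <- which(!done & is.finite(d))
      if (!length(cand)) break
      u <- cand[which.min(d[cand])] # ties: smallest index, deterministic
      done[u] <- TRUE
      for (w in nbrs[[u]]) {
        if (done[w]) next # never re-point finalized nodes: keeps preds acyclic
        nd <- d[u] + effCost[w]
        if (nd < d[w] - 1e-12) {
          d[w] <- nd; pred[w] <- u
        }
      }
    }
    list(d = d, pred = pred)
  }

  while (length(trees) > 1L) {
    effCost <- ifelse(inSolution, 0, ec)
    sp <- lapply(trees, function(tr) dijkstra(tr, effCost))
    bestRatio <- Inf; bestV <- NA_integer_; bestK <- NA_integer_
    bestOrder <- NULL
    for (v in seq_len(n)) {
      dv <- vapply(sp, function(s)
        s$d[v] - effCost[v], numeric(1)) # interior-only path cost to v
      ord <- order(dv)
      dvs <- dv[ord]
      for (k in 2:length(trees)) {
        if (!is.finite(dvs[k])) break
        ratio <- (effCost[v] + sum(dvs[seq_len(k)])) / k
        better <- ratio < bestRatio - 1e-12 ||
          (ratio < bestRatio + 1e-12 &&
             (is.na(bestV) || vn[v] < vn[bestV]))
        if (better) {
          bestRatio <- ratio; bestV <- v; bestK <- k; bestOrder <- ord
        }
      }
    }
    if (!is.finite(bestRatio)) break # cannot merge further
    mergeIdx <- bestOrder[seq_len(bestK)]
    newTree <- unique(c(bestV, unlist(trees[mergeIdx])))
    inSolution[bestV] <- TRUE
    for (j in mergeIdx) { # walk each shortest path back to its tree
      u <- bestV
      pr <- sp[[j]]$pred
      while (!is.na(pr[u])) {
        inSolution[pr[u]] <- TRUE
        newTree <- c(newTree, pr[u])
        u <- pr[u]
      }
    }
    newTree <- unique(newTree)
    inSolution[newTree] <- TRUE
    trees <- c(trees[-mergeIdx], list(newTree))
  }

  solNodes <- vn[inSolution]
  sub <- igraph::induced_subgraph(g, solNodes)
  # realize a spanning tree, then prune non-terminal leaves
  tr <- igraph::mst(sub)
  repeat {
    deg <- igraph::degree(tr)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% terminals)]
    drop <- setdiff(drop, terminals)
    if (!length(drop)) break
    tr <- igraph::delete_vertices(tr, drop)
  }
  el <- igraph::as_edgelist(tr)
  list(nodes = igraph::V(tr)$name,
       edges = data.frame(from = el[, 1], to = el[, 2]))
}
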