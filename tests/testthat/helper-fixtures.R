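# shared fixtures: all built in code, no files

chainNet <- function(n = 7) {
  ids <- sprintf("x%d", seq_len(n))
  directedNetwork(ids[-n], ids[-1])
}

cycleNet <- function(k = 3) {
  ids <- sprintf("c%d", seq_len(k))
  directedNetwork(ids, ids[c(seq_len(k)[-1], 1)])
}

outStarNet <- function(leaves = 3) {
  directedNetwork(rep("hub", leaves), sprintf("l%d", seq_len(leaves)))
}

# Erdos-Renyi digraph over named nodes (deterministic under the caller's seed)
randomDigraph <- function(n, p) {
  m <- matrix(runif(n * n) < p, n, n)
  diag(m) <- FALSE
  idx <- which(m, arr.ind = TRUE)
  ids <- sprintf("n%02d", seq_len(n))
  directedNetwork(ids[idx[, 1]], ids[idx[, 2]], nodes = ids)
}

# exact two-sample rank-sum p by enumeration of all group assignments
enumRankSumP <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  n1 <- length(a)
  combs <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uAll <- apply(combs, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  switch(alternative,
         greater = mean(uAll >= uObs),
         less = mean(uAll <= uObs),
         two.sided = min(1, 2 * min(mean(uAll >= uObs), mean(uAll <= uObs))))
}

# exact Fisher p by direct hypergeometric enumeration over all tables with
# the observed margins (two-sided: sum of probabilities <= observed's)
enumFisherP <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lp <- function(a) {
    b <- rs[1] - a; c0 <- cs[1] - a; d0 <- rs[2] - c0
    if (b < 0 || c0 < 0 || d0 < 0) return(NA_real_)
    lchoose(rs[1], a) + lchoose(rs[2], c0) - lchoose(n, cs[1])
  }
  as <- 0:min(rs[1], cs[1])
  pr <- exp(vapply(as, lp, numeric(1)))
  pObs <- exp(lp(tab[1, 1]))
  sum(pr[!is.na(pr) & pr <= pObs * (1 + 1e-7)])
}

# brute-force node-weighted Steiner optimum: smallest-cost linker subset
# whose union with the terminals induces a connected subgraph spanning them
steinerOptimum <- function(net, terminals, nodeCosts = NULL) {
  g <- asIgraph(net, directed = FALSE)
  vn <- igraph::V(g)$name
  cost <- stats::setNames(rep(1, length(vn)), vn)
  if (!is.null(nodeCosts)) cost[names(nodeCosts)] <- nodeCosts
  others <- setdiff(vn, terminals)
  best <- Inf; bestSet <- NULL
  for (k in 0:length(others)) {
    sets <- if (k == 0) list(character()) else
      asplit(utils::combn(others, k), 2L)
    for (s in sets) {
      s <- as.character(s)
      if (sum(cost[s]) >= best) next
      sub <- igraph::induced_subgraph(g, c(terminals, s))
      comp <- igraph::components(sub)
      if (comp$no == 1L ||
          length(unique(comp$membership[terminals])) == 1L) {
        best <- sum(cost[s]); bestSet <- s
      }
    }
    # unit costs: cost = k, so the first feasible size is optimal
    if (is.null(nodeCosts) && is.finite(best)) break
  }
  list(cost = best, linkers = bestSet)
}

# direct single-pair eQTL simulation: expression = beta*dosage + covariate
# effects + N(0, 1)
simulateEqtlPair <- function(n = 100, beta = 1, maf = 0.3) {
  g <- rbinom(n, 2, maf)
  age <- rnorm(n, 59, 9); sex <- rbinom(n, 1, 0.5)
  y <- beta * g + 0.02 * age + 0.3 * sex + rnorm(n)
  list(y = y, g = g, covar = data.frame(age = age, sex = sex))
}
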