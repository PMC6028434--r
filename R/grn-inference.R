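#' Assemble an expression experiment with sample covariates
#'
#' Wraps a genes-by-samples matrix of normalized log-scale expression and its
#' sample covariates into a [SummarizedExperiment::SummarizedExperiment]
#' (assay `"exprs"`). Covariates used downstream: `disease` (0/1), `hba1c`
#' (percent), `age` (years), `sex` (0/1).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param covariates data.frame with one row per sample, aligned to the
#'   columns of `values` (matched by a `sample` column or by rownames when
#'   present).
#' @return a `SummarizedExperiment`.
#' @export
expressionData <- function(values, covariates) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry gene ids as rownames")
  covariates <- as.data.frame(covariates)
  if ("sample" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample
    covariates$sample <- NULL
  }
  if (!is.null(colnames(values)) && !is.null(rownames(covariates))) {
    miss <- setdiff(colnames(values), rownames(covariates))
    if (length(miss)) stop("covariates missing for samples: ",
                           paste(head(miss), collapse = ", "))
    covariates <- covariates[colnames(values), , drop = FALSE]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(covariates))
}

#' Read an expression TSV (genes in rows) and a covariate TSV
#'
#' @param exprPath TSV whose first column holds gene ids and remaining
#'   columns one sample each.
#' @param covPath TSV keyed by a `sample` column with covariate columns.
#' @return a `SummarizedExperiment` (see [expressionData()]).
#' @export
readExpression <- function(exprPath, covPath) {
  x <- read.table(exprPath, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  cv <- read.table(covPath, header = TRUE, sep = "\t", check.names = FALSE)
  expressionData(as.matrix(x), cv)
}

exprValues <- function(expr) SummarizedExperiment::assay(expr, "exprs")

#' GRN inference configuration
#'
#' @param nVariance genes kept by the variance filter (default 2000).
#' @param nTotal total genes after feature selection (default 2500).
#' @param dePThreshold unadjusted p cutoff for the differential-expression
#'   fill (default 0.05).
#' @param maxParents maximum MRMR parents per target (default 3).
#' @param priorWeight weight of the data-driven causality score versus the
#'   prior regulatory network, in [0, 1] (default 0.75).
#' @param miBins equal-frequency bins for the discrete mutual-information
#'   estimator (default 3).
#' @param scoreRetention edges with combined score strictly greater than this
#'   are retained (default 0).
#' @return a list of class `GrnConfig`.
#' @export
grnConfig <- function(nVariance = 2000L, nTotal = 2500L,
                      dePThreshold = 0.05, maxParents = 3L,
                      priorWeight = 0.75, miBins = 3L,
                      scoreRetention = 0) {
  stopifnot(nVariance <= nTotal, priorWeight >= 0, priorWeight <= 1,
            maxParents >= 1, miBins >= 2)
  structure(list(nVariance = as.integer(nVariance),
                 nTotal = as.integer(nTotal),
                 dePThreshold = dePThreshold,
                 maxParents = as.integer(maxParents),
                 priorWeight = priorWeight, miBins = as.integer(miBins),
                 scoreRetention = scoreRetention),
            class = "GrnConfig")
}

#' Moderated-t differential expression ranking
#'
#' Two-group comparison with empirical-Bayes variance shrinkage: the pooled
#' within-group variance of each gene is shrunk toward the mean gene-wise
#' variance with 4 prior degrees of freedom, and the shifted t statistic is
#' referred to a t distribution on the augmented degrees of freedom. Used
#' only as a ranking statistic for feature selection; genes with no
#' within-group variability fall back on the prior variance rather than
#' dividing by zero.
#'
#' @param expr a `SummarizedExperiment` from [expressionData()].
#' @param contrast `"disease"` (disease status 1 vs 0) or `"hba1c"`
#'   (HbA1c at or above `hba1cCut` vs below).
#' @param hba1cCut dichotomization point for HbA1c, percent (default 6).
#' @return data.frame with columns `gene`, `t`, `p`.
#' @export
differentialRank <- function(expr, contrast = c("disease", "hba1c"),
                             hba1cCut = 6) {
  contrast <- match.arg(contrast)
  x <- exprValues(expr)
  cd <- SummarizedExperiment::colData(expr)
  grp <- if (contrast == "disease") cd$disease == 1
         else cd$hba1c >= hba1cCut
  if (!any(grp) || !any(!grp))
    stop("both phenotype groups must be non-empty for contrast ", contrast)
  n1 <- sum(grp); n2 <- sum(!grp)
  m1 <- rowMeans(x[, grp, drop = FALSE])
  m2 <- rowMeans(x[, !grp, drop = FALSE])
  ss1 <- rowSums((x[, grp, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !grp, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  d0 <- 4; s02 <- mean(s2)
  s2mod <- (d0 * s02 + df * s2) / (d0 + df)
  tstat <- (m1 - m2) / sqrt(s2mod * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = df + d0)
  data.frame(gene = rownames(x), t = tstat, p = p, row.names = NULL)
}

#' Three-step feature selection for GRN construction
#'
#' Selects (a) the `nVariance` most variable genes across all samples, (b)
#' the supplied GWAS genes present on the array, and (c) fills to `nTotal`
#' genes with the top differentially expressed genes not already chosen —
#' ranked by the average of the moderated-t magnitudes over the disease and
#' HbA1c contrasts, restricted to genes with nominal p below `dePThreshold`
#' in at least one contrast. Ties break by gene id, so the result does not
#' depend on input order.
#'
#' @inheritParams differentialRank
#' @param gwasGenes character vector of disease-risk genes (may be empty).
#' @param cfg a [grnConfig()].
#' @return character vector of selected gene ids, length `nTotal` when enough
#'   eligible genes exist (otherwise shorter, with a warning).
#' @export
selectFeatures <- function(expr, gwasGenes = character(),
                           cfg = grnConfig()) {
  x <- exprValues(expr)
  genes <- rownames(x)
  v <- apply(x, 1L, var)
  ordv <- genes[order(-v, genes)]
  chosen <- ordv[seq_len(min(cfg$nVariance, length(genes)))]
  chosen <- union(chosen, intersect(gwasGenes, genes))
  need <- cfg$nTotal - length(chosen)
  if (need > 0) {
    d1 <- differentialRank(expr, "disease")
    d2 <- differentialRank(expr, "hba1c")
    stat <- (abs(d1$t) + abs(d2$t)) / 2
    elig <- (d1$p < cfg$dePThreshold | d2$p < cfg$dePThreshold) &
      !(d1$gene %in% chosen)
    pool <- d1$gene[elig][order(-stat[elig], d1$gene[elig])]
    if (length(pool) < need)
      warning("only ", length(pool), " eligible DE genes to fill ", need,
              " slots; returning a shorter list")
    chosen <- c(chosen, pool[seq_len(min(need, length(pool)))])
  }
  sort(chosen)
}

## ---- discrete mutual information -------------------------------------------

# equal-frequency discretization; ties share a bin via average ranks, so a
# constant vector collapses to a single bin (MI contribution 0)
discretizeEf <- function(x, bins) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(bins * r / length(x))
  as.integer(pmin(pmax(b, 1L), bins))
}

miFromCounts <- function(counts, n) {
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information of two continuous vectors
#'
#' Discretizes both vectors into `bins` equal-frequency categories and
#' returns the discrete mutual information in nats. Non-negative and
#' symmetric; a constant vector yields 0.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param bins number of equal-frequency bins (default 3).
#' @return mutual information in nats.
#' @export
mutualInformation <- function(x, y, bins = 3L) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  dx <- discretizeEf(x, bins); dy <- discretizeEf(y, bins)
  n <- length(x)
  counts <- matrix(tabulate((dx - 1L) * bins + dy, bins * bins),
                   nrow = bins, byrow = TRUE)
  max(0, miFromCounts(counts, n))
}

entropyDisc <- function(d, bins) {
  p <- tabulate(d, bins) / length(d)
  -sum(p[p > 0] * log(p[p > 0]))
}

miDisc <- function(dx, dy, bins) {
  n <- length(dx)
  counts <- matrix(tabulate((dx - 1L) * bins + dy, bins * bins),
                   nrow = bins, byrow = TRUE)
  max(0, miFromCounts(counts, n))
}

cmiDisc <- function(dx, dy, dz, bins) {
  n <- length(dx)
  out <- 0
  for (z in seq_len(bins)) {
    sel <- dz == z
    nz <- sum(sel)
    if (nz < 2) next
    counts <- matrix(tabulate((dx[sel] - 1L) * bins + dy[sel], bins * bins),
                     nrow = bins, byrow = TRUE)
    out <- out + (nz / n) * miFromCounts(counts, nz)
  }
  max(0, out)
}

# all pairwise MIs between rows of a pre-discretized matrix, via per-bin
# indicator cross-products (exact, fast for a few hundred genes)
miMatrixDisc <- function(D, bins) {
  n <- ncol(D)
  ind <- lapply(seq_len(bins), function(k) (D == k) * 1)
  marg <- vapply(ind, rowSums, numeric(nrow(D))) / n # genes x bins
  mi <- matrix(0, nrow(D), nrow(D), dimnames = list(rownames(D), rownames(D)))
  for (k in seq_len(bins)) for (l in seq_len(bins)) {
    pj <- (ind[[k]] %*% t(ind[[l]])) / n
    pm <- outer(marg[, k], marg[, l])
    term <- pj * log(pj / pm)
    term[pj == 0] <- 0
    mi <- mi + term
  }
  mi[mi < 0] <- 0
  diag(mi) <- NA
  mi
}

#' MRMR parent selection for one target gene
#'
#' Greedy maximum-relevance minimum-redundancy selection: the first parent
#' maximizes MI with the target; each further parent maximizes
#' `MI(candidate, target) - mean(MI(candidate, chosen parents))`. Selection
#' stops at `maxParents` or when no candidate remains. Ties break by gene id.
#'
#' @inheritParams differentialRank
#' @param target target gene id.
#' @param candidates candidate parent gene ids (target excluded).
#' @param cfg a [grnConfig()].
#' @return character vector of parents in selection order (possibly empty).
#' @export
mrmrParents <- function(expr, target, candidates, cfg = grnConfig()) {
  candidates <- setdiff(candidates, target)
  if (!length(candidates)) return(character())
  x <- exprValues(expr)
  D <- t(apply(x[c(target, candidates), , drop = FALSE], 1L,
               discretizeEf, bins = cfg$miBins))
  mi <- miMatrixDisc(D, cfg$miBins)
  mrmrFromMi(mi, target, candidates, cfg$maxParents)
}

mrmrFromMi <- function(mi, target, candidates, maxParents) {
  chosen <- character()
  avail <- candidates
  while (length(chosen) < maxParents && length(avail)) {
    rel <- mi[avail, target]
    red <- if (length(chosen))
      rowMeans(mi[avail, chosen, drop = FALSE]) else 0
    sc <- rel - red
    pick <- avail[order(-sc, avail)][1L]
    chosen <- c(chosen, pick)
    avail <- setdiff(avail, pick)
  }
  chosen
}

#' Causality (v-structure) score of a parent
#'
#' Scores the orientation evidence for `parent -> target` from its co-parents:
#' for each co-parent q the collider contrast
#' `[CMI(parent; q | target) - MI(parent; q)] / min(H(parent), H(q))`
#' is computed on the discretized profiles, and the mean over co-parents is
#' clipped to [-1, 1]. Conditioning on a common child induces dependence
#' between otherwise independent parents, so a positive score is collider
#' (v-structure) evidence anchoring the edge toward the target; a parent with
#' no co-parents scores 0.
#'
#' @inheritParams mrmrParents
#' @param parent a selected parent of `target`.
#' @param coparents the other selected parents.
#' @return numeric score in [-1, 1].
#' @export
causalityScore <- function(expr, target, parent, coparents,
                           cfg = grnConfig()) {
  if (!length(coparents)) return(0)
  x <- exprValues(expr)
  bins <- cfg$miBins
  dt <- discretizeEf(x[target, ], bins)
  dp <- discretizeEf(x[parent, ], bins)
  hp <- entropyDisc(dp, bins)
  vals <- vapply(coparents, function(q) {
    dq <- discretizeEf(x[q, ], bins)
    hn <- min(hp, entropyDisc(dq, bins))
    if (hn <= 0) return(0)
    (cmiDisc(dp, dq, dt, bins) - miDisc(dp, dq, bins)) / hn
  }, numeric(1))
  min(1, max(-1, mean(vals)))
}

#' Combine data-driven edge scores with a prior regulatory network
#'
#' The combined score of an edge is
#' `priorWeight * causality_score + (1 - priorWeight) * prior_indicator`,
#' where the causality score is 0 for edges not selected by MRMR and the
#' prior indicator is 1 for edges of the prior network. Edges with combined
#' score strictly greater than `scoreRetention` (default 0) are retained, so
#' a prior-only edge survives with score `1 - priorWeight` while a data edge
#' with negative causality evidence and no prior support is dropped.
#'
#' @param scored data.frame with columns `parent`, `target`,
#'   `causality_score` (and optionally `mrmr_rank`).
#' @param prior a [DirectedNetwork-class] of known regulatory edges, or NULL.
#' @param cfg a [grnConfig()].
#' @param geneUniverse restrict prior edges to these genes (default: genes
#'   appearing in `scored`).
#' @return list with `network` (a [DirectedNetwork-class]) and `table`
#'   (the scored edge set with combined scores, retained edges only).
#' @export
combineWithPrior <- function(scored, prior = NULL, cfg = grnConfig(),
                             geneUniverse = NULL) {
  if (is.null(geneUniverse))
    geneUniverse <- unique(c(scored$parent, scored$target))
  pe <- if (is.null(prior)) data.frame(from = character(), to = character())
        else edgeTable(prior)
  pe <- pe[pe$from %in% geneUniverse & pe$to %in% geneUniverse, , drop = FALSE]
  priorKey <- paste(pe$from, pe$to, sep = "\r")
  dataKey <- if (nrow(scored)) paste(scored$parent, scored$target, sep = "\r")
             else character()
  allKey <- union(dataKey, priorKey)
  if (!length(allKey)) {
    tab <- data.frame(parent = character(), target = character(),
                      causality_score = numeric(), prior = logical(),
                      combined_score = numeric())
    return(list(network = directedNetwork(nodes = geneUniverse),
                table = tab))
  }
  parts <- do.call(rbind, strsplit(allKey, "\r", fixed = TRUE))
  dscore <- setNames(rep(0, length(allKey)), allKey)
  if (nrow(scored)) dscore[dataKey] <- scored$causality_score
  hasPrior <- allKey %in% priorKey
  combined <- cfg$priorWeight * dscore +
    (1 - cfg$priorWeight) * as.numeric(hasPrior)
  keep <- combined > cfg$scoreRetention
  tab <- data.frame(parent = parts[, 1], target = parts[, 2],
                    causality_score = unname(dscore),
                    prior = hasPrior, combined_score = unname(combined),
                    row.names = NULL)[keep, , drop = FALSE]
  prov <- ifelse(tab$prior & tab$causality_score != 0, "prior,regulatory",
                 ifelse(tab$prior, "prior", "regulatory"))
  net <- directedNetwork(tab$parent, tab$target, provenance = prov,
                         score = tab$combined_score)
  list(network = net, table = tab)
}

#' Infer a gene-regulatory network from expression data
#'
#' End-to-end GRN construction: feature selection ([selectFeatures()]), MRMR
#' parent selection per target over the candidate pool, causality scoring of
#' every selected edge, and combination with the prior regulatory network
#' ([combineWithPrior()]). When a prior is supplied the candidate parents are
#' restricted to selected genes with outgoing prior edges (regulators);
#' otherwise all selected genes are candidates.
#'
#' @inheritParams selectFeatures
#' @param prior optional [DirectedNetwork-class] of known regulatory edges.
#' @param genes optional precomputed feature set (skips [selectFeatures()]).
#' @return list with `network`, `table` (see [combineWithPrior()]) and
#'   `genes` (the selected feature set).
#' @export
inferGrn <- function(expr, prior = NULL, gwasGenes = character(),
                     cfg = grnConfig(), genes = NULL) {
  if (is.null(genes)) genes <- selectFeatures(expr, gwasGenes, cfg)
  x <- exprValues(expr)[genes, , drop = FALSE]
  pool <- if (!is.null(prior))
    intersect(genes, unique(edgeTable(prior)$from)) else genes
  D <- t(apply(x, 1L, discretizeEf, bins = cfg$miBins))
  rownames(D) <- genes
  mi <- miMatrixDisc(D, cfg$miBins)
  dx <- lapply(seq_len(nrow(D)), function(i) D[i, ])
  names(dx) <- genes
  rows <- vector("list", length(genes))
  for (ti in seq_along(genes)) {
    tg <- genes[ti]
    cand <- setdiff(pool, tg)
    if (!length(cand)) next
    parents <- mrmrFromMi(mi, tg, cand, cfg$maxParents)
    if (!length(parents)) next
    cs <- vapply(parents, function(p) {
      cop <- setdiff(parents, p)
      if (!length(cop)) return(0)
      hp <- entropyDisc(dx[[p]], cfg$miBins)
      vals <- vapply(cop, function(q) {
        hn <- min(hp, entropyDisc(dx[[q]], cfg$miBins))
        if (hn <= 0) return(0)
        (cmiDisc(dx[[p]], dx[[q]], dx[[tg]], cfg$miBins) -
            miDisc(dx[[p]], dx[[q]], cfg$miBins)) / hn
      }, numeric(1))
      min(1, max(-1, mean(vals)))
    }, numeric(1))
    rows[[ti]] <- data.frame(parent = parents, target = tg,
                             mrmr_rank = seq_along(parents),
                             causality_score = unname(cs),
                             row.names = NULL)
  }
  scored <- do.call(rbind, rows)
  if (is.null(scored))
    scored <- data.frame(parent = character(), target = character(),
                         mrmr_rank = integer(), causality_score = numeric())
  res <- combineWithPrior(scored, prior, cfg, geneUniverse = genes)
  res$genes <- genes
  res$scoredEdges <- scored
  res
}
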