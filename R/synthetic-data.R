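#' Generate a layered regulatory network with known ground truth
#'
#' Builds a hierarchical directed network emulating the structure the
#' high-control-centrality hypothesis assumes: genes are split into
#' `nLayers` layers, edges run predominantly from layer k to layer k+1, and
#' a fraction of back-edges creates feedback cycles. Layer-1 genes — the
#' upstream regulators whose control reaches the whole hierarchy — are
#' recorded as the controller set. A fixed subset of deepest-layer genes is
#' recorded as the disease gene set (the genes shifted in cases by
#' [simulateExpression()]).
#'
#' @param nGenes number of genes (default 300).
#' @param nLayers number of layers (default 5, >= 2).
#' @param outDegreeMean mean forward out-degree per non-terminal gene
#'   (default 2); must be below the genes-per-layer count.
#' @param cycleFraction back-edges added as a fraction of the forward edge
#'   count (default 0.1); 0 gives a DAG.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `network` (a [DirectedNetwork-class]) and `truth`
#'   (class `SyntheticTruth`: `edges`, `controller_genes`, `disease_genes`,
#'   `layers`, `params`).
#' @export
generateRegulatoryNetwork <- function(nGenes = 300L, nLayers = 5L,
                                      outDegreeMean = 2, cycleFraction = 0.1,
                                      seed = 1L) {
  stopifnot(nLayers >= 2, nGenes >= 2 * nLayers)
  perLayer <- ceiling(nGenes / nLayers)
  if (outDegreeMean >= perLayer)
    stop("outDegreeMean must be below the genes-per-layer count (",
         perLayer, ")")
  withr::local_seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  layer <- rep(seq_len(nLayers), each = perLayer, length.out = nGenes)
  byLayer <- split(genes, layer)

  from <- character(); to <- character()
  for (k in seq_len(nLayers - 1L)) {
    nxt <- byLayer[[k + 1L]]
    for (gsrc in byLayer[[k]]) {
      nOut <- max(1L, rpois(1L, outDegreeMean))
      tgt <- sample(nxt, min(nOut, length(nxt)))
      from <- c(from, rep(gsrc, length(tgt))); to <- c(to, tgt)
    }
  }
  nBack <- round(cycleFraction * length(from))
  if (nBack > 0) {
    src <- sample(genes[layer > 1L], nBack, replace = TRUE)
    bto <- vapply(src, function(gsrc) {
      up <- genes[layer < layer[match(gsrc, genes)]]
      sample(up, 1L)
    }, character(1))
    keep <- src != bto
    from <- c(from, src[keep]); to <- c(to, bto[keep])
  }
  net <- directedNetwork(from, to, provenance = "regulatory", nodes = genes)
  deepest <- byLayer[[nLayers]]
  diseaseGenes <- sort(sample(deepest, max(5L, round(0.3 * length(deepest)))))
  truth <- structure(list(
    edges = edgeTable(net)[, c("from", "to")],
    controller_genes = byLayer[[1L]],
    disease_genes = diseaseGenes,
    layers = setNames(layer, genes),
    planted_eqtl = NULL,
    params = list(nGenes = nGenes, nLayers = nLayers,
                  outDegreeMean = outDegreeMean,
                  cycleFraction = cycleFraction, seed = seed)),
    class = "SyntheticTruth")
  list(network = net, truth = truth)
}

#' Simulate expression from the network via a linear SEM
#'
#' Draws each sample from the linear structural-equation model
#' `x = (I - W)^(-1) e`, `e ~ N(0, noiseSd^2)`, where `W[child, parent]`
#' carries `edgeWeight` for every network edge (rescaled when the spectral
#' radius reaches 1, so cyclic networks have a stable equilibrium). A
#' disease indicator (default 15% of samples, mirroring a 9/63 case/control
#' imbalance) shifts the truth's disease gene set by `diseaseEffect`; HbA1c
#' is a continuous covariate correlated with disease status, and age and sex
#' are randomized.
#'
#' @param net a [DirectedNetwork-class].
#' @param truth the `SyntheticTruth` from [generateRegulatoryNetwork()].
#' @param nSamples number of samples (default 63).
#' @param edgeWeight planted SEM edge weight (default 0.8).
#' @param noiseSd exogenous noise standard deviation (default 1).
#' @param diseaseEffect expression shift in cases for the disease gene set
#'   (default 1).
#' @param diseaseFraction fraction of case samples (default 0.15).
#' @param seed integer seed.
#' @return a `SummarizedExperiment` (see [expressionData()]).
#' @export
simulateExpression <- function(net, truth, nSamples = 63L, edgeWeight = 0.8,
                               noiseSd = 1, diseaseEffect = 1,
                               diseaseFraction = 0.15, seed = 1L) {
  withr::local_seed(seed)
  genes <- nodeIds(net)
  n <- length(genes)
  e <- edgeTable(net)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  W[cbind(match(e$to, genes), match(e$from, genes))] <- edgeWeight
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho >= 1) {
    W <- W * (0.95 / rho)
    rho2 <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rho2 >= 1) stop("SEM weight matrix could not be stabilized")
  }
  A <- solve(diag(n) - W)
  E <- matrix(rnorm(n * nSamples, sd = noiseSd), n, nSamples)
  X <- A %*% E
  dimnames(X) <- list(genes, sprintf("S%03d", seq_len(nSamples)))

  nCase <- max(1L, round(diseaseFraction * nSamples))
  disease <- c(rep(1L, nCase), rep(0L, nSamples - nCase))[sample(nSamples)]
  shifted <- intersect(truth$disease_genes, genes)
  X[shifted, disease == 1L] <- X[shifted, disease == 1L] + diseaseEffect
  covar <- data.frame(
    sample = colnames(X),
    disease = disease,
    hba1c = round(5.5 + 1.7 * disease + rnorm(nSamples, sd = 0.5), 2),
    age = round(rnorm(nSamples, 59, 9)),
    sex = rbinom(nSamples, 1L, 0.5))
  expressionData(X, covar)
}

#' Generate pathway gene sets with one planted controller pathway
#'
#' The `"CONTROLLER"` set samples from the truth's controller genes (the
#' layer-1 regulators), decoy sets sample uniformly from all genes, and an
#' optional `"CANCER_DECOY"` set exercises the cancer-name exclusion filter.
#'
#' @param truth a `SyntheticTruth`.
#' @param nDecoys number of decoy sets (default 20).
#' @param setSize genes per set (default 15).
#' @param seed integer seed.
#' @param includeCancerDecoy add a `"CANCER_DECOY"` set (default TRUE).
#' @return named list of gene vectors.
#' @export
generatePathways <- function(truth, nDecoys = 20L, setSize = 15L, seed = 1L,
                             includeCancerDecoy = TRUE) {
  withr::local_seed(seed)
  genes <- names(truth$layers)
  sets <- list(CONTROLLER = sort(sample(truth$controller_genes,
                                        min(setSize,
                                            length(truth$controller_genes)))))
  for (k in seq_len(nDecoys))
    sets[[sprintf("DECOY_%02d", k)]] <- sort(sample(genes, setSize))
  if (includeCancerDecoy)
    sets[["CANCER_DECOY"]] <- sort(sample(genes, setSize))
  sets
}

#' Generate genotypes with planted cis effects
#'
#' Places gene g (in network node order) on a synthetic coordinate system —
#' chromosome 1, start `1e6 * g + 1`, length 10 kb, so 250 kb cis windows of
#' neighboring genes never overlap. SNP dosages are Binomial(2, MAF) with
#' MAF uniform in `mafRange`. `nPlanted` genes get a cis SNP (placed inside
#' their window) whose dosage is added to their expression scaled by `beta`;
#' the remaining SNPs split between cis positions of random genes (no
#' effect) and gene deserts.
#'
#' @param truth a `SyntheticTruth` (updated copy is returned).
#' @param expr the `SummarizedExperiment` to spike (a modified copy is
#'   returned).
#' @param nSnps total SNPs (default 60).
#' @param nPlanted planted cis effects (default 5).
#' @param mafRange minor-allele-frequency range (default c(0.1, 0.4)).
#' @param beta planted effect size per dosage unit (default 1).
#' @param seed integer seed.
#' @return list with `geno` ([GenotypeMatrix-class]), `annot`
#'   (gene [GenomicRanges::GRanges]), `expr` (spiked), `truth` (with
#'   `planted_eqtl` filled in).
#' @export
generateGenotypes <- function(truth, expr, nSnps = 60L, nPlanted = 5L,
                              mafRange = c(0.1, 0.4), beta = 1, seed = 1L) {
  stopifnot(nPlanted <= nSnps)
  withr::local_seed(seed)
  genes <- names(truth$layers)
  nSamples <- ncol(exprValues(expr))
  gi <- seq_along(genes)
  annot <- geneAnnotation(data.frame(
    gene = genes, chr = "1", start = 1e6 * gi + 1, end = 1e6 * gi + 1e4))

  plantedGenes <- sort(sample(genes, nPlanted))
  cisNull <- sample(setdiff(genes, plantedGenes),
                    min(length(genes) - nPlanted,
                        ceiling((nSnps - nPlanted) / 2)))
  nDesert <- nSnps - nPlanted - length(cisNull)

  pos <- c(1e6 * match(plantedGenes, genes) - 50000,   # inside cis window
           1e6 * match(cisNull, genes) + 1e4 + 100000, # cis, no effect
           1e6 * sample(gi, nDesert, replace = TRUE) + 500000) # desert
  snp <- sprintf("rs%05d", seq_len(nSnps))
  maf <- runif(nSnps, mafRange[1], mafRange[2])
  d <- t(vapply(maf, function(m) rbinom(nSamples, 2L, m),
                numeric(nSamples)))
  rownames(d) <- snp
  colnames(d) <- colnames(exprValues(expr))
  geno <- genotypeMatrix(d, data.frame(snp = snp, chr = "1", pos = pos))

  x <- exprValues(expr)
  for (k in seq_len(nPlanted))
    x[plantedGenes[k], ] <- x[plantedGenes[k], ] + beta * d[k, ]
  expr2 <- expressionData(
    x, as.data.frame(SummarizedExperiment::colData(expr)))

  truth$planted_eqtl <- data.frame(snp = snp[seq_len(nPlanted)],
                                   gene = plantedGenes, beta = beta)
  list(geno = geno, annot = annot, expr = expr2, truth = truth)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a full study's worth of inputs with known ground truth —
#' network, expression + covariates, prior/kinase/signaling edge lists,
#' pathway GMT, disease gene lists, genotypes and gene annotation — and
#' writes them as plain-text files plus a `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param nGenes,nLayers,nSamples,nDecoys,nSnps,nPlanted generator sizes.
#' @param seed integer master seed.
#' @return invisibly, a named list of the written paths plus the truth.
#' @export
writeSyntheticBundle <- function(dir, nGenes = 300L, nLayers = 5L,
                                 nSamples = 63L, nDecoys = 20L,
                                 nSnps = 60L, nPlanted = 5L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateRegulatoryNetwork(nGenes, nLayers, seed = seed)
  expr <- simulateExpression(gen$network, gen$truth, nSamples = nSamples,
                             seed = seed + 1L)
  sets <- generatePathways(gen$truth, nDecoys = nDecoys, seed = seed + 2L)
  gg <- generateGenotypes(gen$truth, expr, nSnps = nSnps,
                          nPlanted = nPlanted, seed = seed + 3L)
  truth <- gg$truth
  expr <- gg$expr
  withr::local_seed(seed + 4L)
  genes <- nodeIds(gen$network)
  e <- edgeTable(gen$network)
  priorIdx <- sort(sample(nrow(e), round(0.3 * nrow(e))))
  extra <- function(m) { # random extra edges among existing genes
    f <- sample(genes, m, replace = TRUE); t <- sample(genes, m, replace = TRUE)
    keep <- f != t
    data.frame(from = f[keep], to = t[keep])
  }
  kin <- extra(round(0.05 * nrow(e))); sig <- extra(round(0.05 * nrow(e)))
  gwasSeed <- sort(sample(genes, 25L))
  gold <- sort(unique(c(sample(truth$disease_genes,
                               round(0.6 * length(truth$disease_genes))),
                        sample(genes, 10L))))
  gwasDis <- sort(unique(c(sample(truth$disease_genes,
                                  round(0.5 * length(truth$disease_genes))),
                           sample(genes, 15L))))

  p <- function(f) file.path(dir, f)
  x <- exprValues(expr)
  write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
              p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cv <- as.data.frame(SummarizedExperiment::colData(expr))
  write.table(data.frame(sample = rownames(cv), cv),
              p("covariates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(e[priorIdx, c("from", "to")], p("prior_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(kin, p("kinase_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sig, p("signaling_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeGmt(sets, p("pathways.gmt"))
  writeLines(gwasSeed, p("construction_gwas_genes.txt"))
  writeLines(gold, p("gold_genes.txt"))
  writeLines(gwasDis, p("gwas_disease_genes.txt"))
  sp <- snpPositions(gg$geno)
  write.table(data.frame(sp, dosages(gg$geno), check.names = FALSE),
              p("genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gr <- gg$annot
  write.table(data.frame(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::end(gr), names(gr)),
              p("gene_annotation.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(controller_genes = truth$controller_genes,
         disease_genes = truth$disease_genes,
         planted_eqtl = truth$planted_eqtl,
         layers = as.list(truth$layers),
         params = truth$params),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, truth = truth,
                 files = list.files(dir, full.names = TRUE)))
}
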