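#' Read / write gene-set collections in GMT format
#'
#' `readGmt()` wraps `fgsea::gmtPathways()` and returns a named list of gene
#' vectors; `writeGmt()` writes one (name, description, genes...) line per
#' set.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(g) unique(trimws(g)))
}

#' @rdname readGmt
#' @param sets named list of gene vectors.
#' @param description optional description column (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets), !anyDuplicated(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], rep_len(description, length(sets))[i],
            sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line list
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  unique(g[nzchar(g) & !grepl("^#", g)])
}

defaultCancerKeywords <- c("cancer", "carcinoma", "leukemia", "melanoma",
                           "glioma")

#' High-control-centrality (HiCc) pathways
#'
#' For every pathway with at least `minOverlap` genes in the network, tests
#' whether the control-centrality distribution of its member genes is
#' stochastically greater than that of all other network genes (one-sided
#' Mann-Whitney U). Pathways below the p cutoff are flagged HiCc. Pathways
#' whose names match a cancer keyword are removed when `excludeCancer` is
#' TRUE; pathways with too few network genes are reported as untested
#' (`tested = FALSE`, NA statistics).
#'
#' @param cc a [CcResult-class] computed on the analyzed network.
#' @param pathways named list of gene vectors (see [readGmt()]).
#' @param pCut significance cutoff (default 0.05).
#' @param minOverlap minimum pathway genes in the network (default 5).
#' @param excludeCancer drop cancer-keyword pathways (default TRUE).
#' @param cancerKeywords keywords matched case-insensitively against pathway
#'   names.
#' @return data.frame with one row per pathway: `pathway`, `n_in_network`,
#'   `U`, `p`, `mean_cc_in`, `tested`, `is_hicc`.
#' @export
hiccPathways <- function(cc, pathways, pCut = 0.05, minOverlap = 5L,
                         excludeCancer = TRUE,
                         cancerKeywords = defaultCancerKeywords) {
  stopifnot(is(cc, "CcResult"))
  if (excludeCancer) {
    pat <- paste(cancerKeywords, collapse = "|")
    pathways <- pathways[!grepl(pat, names(pathways), ignore.case = TRUE)]
  }
  vals <- ccValues(cc)
  genes <- names(vals)
  rows <- lapply(names(pathways), function(nm) {
    inset <- intersect(pathways[[nm]], genes)
    n <- length(inset)
    if (n < minOverlap)
      return(data.frame(pathway = nm, n_in_network = n, U = NA_real_,
                        p = NA_real_, mean_cc_in = NA_real_,
                        tested = FALSE, is_hicc = FALSE))
    a <- vals[inset]; b <- vals[setdiff(genes, inset)]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                       exact = FALSE, correct = TRUE))
    data.frame(pathway = nm, n_in_network = n,
               U = unname(wt$statistic), p = wt$p.value,
               mean_cc_in = mean(a), tested = TRUE,
               is_hicc = wt$p.value < pCut)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Control centrality versus a degree-preserving randomized ensemble
#'
#' Rewires the network `nRandom` times with degree-preserving double edge
#' swaps, recomputes every node's control centrality on each randomization,
#' and returns the two-sided rank-sum p-value of the real Cc distribution
#' against each randomized one together with the mean Cc per network.
#'
#' @param net a [DirectedNetwork-class].
#' @param nRandom ensemble size (default 100).
#' @param seed integer seed.
#' @param nTrials Krylov trials per Cc call (default 3).
#' @return list with `observed_mean`, `random_means` (length `nRandom`),
#'   and `p_values` (length `nRandom`, two-sided Mann-Whitney).
#' @export
ccVsRandomEnsemble <- function(net, nRandom = 100L, seed = 1L,
                               nTrials = 3L) {
  stopifnot(nRandom >= 1)
  obs <- ccValues(controlCentralityAll(net, nTrials = nTrials, seed = seed))
  pvals <- numeric(nRandom); means <- numeric(nRandom)
  for (k in seq_len(nRandom)) {
    rnet <- rewireNetwork(net, seed = seed + k)
    rcc <- ccValues(controlCentralityAll(rnet, nTrials = nTrials,
                                         seed = seed + k))
    means[k] <- mean(rcc)
    pvals[k] <- suppressWarnings(
      wilcox.test(obs, rcc, exact = FALSE))$p.value
  }
  list(observed_mean = mean(obs), random_means = means, p_values = pvals)
}

#' Disease-gene enrichment of each pathway
#'
#' One-sided (greater) Fisher exact test of the overlap between each pathway
#' and a disease gene set, both intersected with the gene universe (normally
#' the genes of the analyzed network). Genes used to construct the network
#' (e.g. GWAS seed genes) should be removed from `diseaseGenes` by the
#' caller before testing to avoid circularity.
#'
#' @param pathways named list of gene vectors.
#' @param diseaseGenes character vector of disease-associated genes.
#' @param universe background gene universe.
#' @param pCut enrichment cutoff (default 0.05).
#' @return data.frame with `pathway`, `n_pathway`, `n_overlap`, `p`,
#'   `enriched`.
#' @export
pathwayEnrichment <- function(pathways, diseaseGenes, universe,
                              pCut = 0.05) {
  universe <- unique(universe)
  disease <- intersect(diseaseGenes, universe)
  if (!length(disease) || !length(universe))
    stop("disease gene set does not intersect the universe")
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    a <- length(intersect(pw, disease))
    b <- length(pw) - a
    c0 <- length(disease) - a
    d0 <- length(universe) - length(pw) - c0
    p <- fisher.test(matrix(c(a, b, c0, d0), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(pathway = nm, n_pathway = length(pw), n_overlap = a,
               p = p, enriched = p < pCut)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast enrichment rates between HiCc and non-HiCc pathways
#'
#' Builds the 2x2 table (HiCc enriched / not; non-HiCc enriched / not) and
#' returns the two-tailed Fisher exact p-value and odds ratio — the test of
#' whether disease-gene enrichment concentrates in high-control pathways.
#'
#' @param hiccFlags named logical vector: pathway is HiCc.
#' @param enrichedFlags named logical vector over the same pathways: pathway
#'   is enriched in the disease gene set.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
hiccEnrichmentContrast <- function(hiccFlags, enrichedFlags) {
  if (!is.null(names(hiccFlags)) && !is.null(names(enrichedFlags))) {
    common <- intersect(names(hiccFlags), names(enrichedFlags))
    if (!setequal(names(hiccFlags), names(enrichedFlags)))
      warning("flag vectors disagree on pathways; using the intersection")
    hiccFlags <- hiccFlags[common]; enrichedFlags <- enrichedFlags[common]
  }
  stopifnot(length(hiccFlags) == length(enrichedFlags))
  if (!any(hiccFlags) || !any(!hiccFlags))
    stop("both HiCc and non-HiCc groups must be non-empty")
  tab <- matrix(c(sum(hiccFlags & enrichedFlags),
                  sum(hiccFlags & !enrichedFlags),
                  sum(!hiccFlags & enrichedFlags),
                  sum(!hiccFlags & !enrichedFlags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("HiCc", "non-HiCc"),
                                c("enriched", "not_enriched")))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
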