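#' Derive a per-stage seed from the global seed
#'
#' Fans the single pipeline seed out to independent per-stage seeds by
#' hashing the stage name (31-ary rolling hash mod a prime below 2^31) and
#' mixing in the global seed, so adding a stage never shifts the random
#' stream of another.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
stageSeed <- function(seed, stage) {
  p <- 2147480009 # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% p
  as.integer((h + (as.numeric(seed) %% p) * 2654435) %% (p - 1) + 1)
}

#' Pipeline configuration
#'
#' Collects input paths and stage parameters for [runPipeline()]. `paths`
#' entries that are NULL (or missing files at run time) cause dependent
#' stages to be skipped gracefully. Can be populated from a flat YAML file.
#'
#' @param paths named list of input paths: `expression`, `covariates`
#'   (required); `prior`, `kinase`, `signaling`, `pathways`,
#'   `constructionGwas`, `gold`, `gwasDisease`, `genotypes`, `annotation`
#'   (optional).
#' @param outDir output directory for stage TSVs and the manifest.
#' @param grn a [grnConfig()].
#' @param pCut HiCc / enrichment significance cutoff (default 0.05).
#' @param minOverlap minimum pathway genes in network (default 5).
#' @param excludeCancer drop cancer-named pathways (default TRUE).
#' @param nRandom randomized networks for topology z-scores (default 100).
#' @param windowBp cis window (default 250000).
#' @param fdrCut eQTL FDR threshold (default 0.01).
#' @param nPerm permutations for eQTL permutation p (default 10000).
#' @param legacyPermFloor see [permutationP()] (default TRUE).
#' @param seed global seed (default 1).
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(paths, outDir, grn = grnConfig(),
                           pCut = 0.05, minOverlap = 5L,
                           excludeCancer = TRUE, nRandom = 100L,
                           windowBp = 250000L, fdrCut = 0.01,
                           nPerm = 10000L, legacyPermFloor = TRUE,
                           seed = 1L) {
  stopifnot(fdrCut > 0, fdrCut < 1,
            all(c("expression", "covariates") %in% names(paths)))
  structure(list(paths = paths, outDir = outDir, grn = grn, pCut = pCut,
                 minOverlap = as.integer(minOverlap),
                 excludeCancer = excludeCancer,
                 nRandom = as.integer(nRandom),
                 windowBp = as.integer(windowBp), fdrCut = fdrCut,
                 nPerm = as.integer(nPerm),
                 legacyPermFloor = legacyPermFloor,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a PipelineConfig from a flat YAML file
#'
#' Path keys go under `paths:`; every other key matches a
#' [pipelineConfig()] or [grnConfig()] argument.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  grnArgs <- y[intersect(names(y), names(formals(grnConfig)))]
  rest <- y[setdiff(names(y), c(names(grnArgs), "paths", "outDir"))]
  rest <- rest[intersect(names(rest), names(formals(pipelineConfig)))]
  do.call(pipelineConfig,
          c(list(paths = y$paths, outDir = y$outDir,
                 grn = do.call(grnConfig, grnArgs)), rest))
}

hasPath <- function(cfg, key) {
  p <- cfg$paths[[key]]
  !is.null(p) && file.exists(p)
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: feature selection, GRN inference, EGRN
#' assembly (merge with kinase/signaling edges, largest connected
#' component), topology diagnostics, control centrality, HiCc pathway
#' ranking, disease-gene enrichment contrasts, cis-eQTL mapping of HiCc
#' pathway genes, and Steiner-tree connection of the FDR-passing eQTL
#' genes. Every stage writes its table under `cfg$outDir`; a
#' `manifest.json` records parameters, per-stage seeds, row counts and
#' status (`completed` / `skipped` / `failed`). Stages whose inputs are
#' absent are skipped; a stage failure is recorded and later dependent
#' stages are skipped, with earlier outputs preserved.
#'
#' @param cfg a [pipelineConfig()].
#' @return the manifest, invisibly (a named list).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), "paths")],
                   paths = cfg$paths, stages = list())
  env <- new.env()
  note <- function(stage, status, n = NA)
    manifest$stages[[stage]] <<- list(status = status, rows = n,
                                      seed = stageSeed(cfg$seed, stage))
  runStage <- function(stage, fun, needed = TRUE) {
    if (!isTRUE(needed)) { note(stage, "skipped"); return(invisible()) }
    res <- tryCatch(fun(stageSeed(cfg$seed, stage)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, paste("failed:", conditionMessage(res)))
    } else note(stage, "completed", res)
  }
  out <- function(f) file.path(cfg$outDir, f)

  runStage("features", function(s) {
    env$expr <- readExpression(cfg$paths$expression, cfg$paths$covariates)
    env$gwasSeed <- if (hasPath(cfg, "constructionGwas"))
      readGeneList(cfg$paths$constructionGwas) else character()
    env$genes <- selectFeatures(env$expr, env$gwasSeed, cfg$grn)
    writeLines(env$genes, out("selected_genes.txt"))
    length(env$genes)
  })

  runStage("grn", function(s) {
    prior <- if (hasPath(cfg, "prior"))
      readNetwork(cfg$paths$prior, provenance = "prior") else NULL
    env$grn <- inferGrn(env$expr, prior, env$gwasSeed, cfg$grn,
                        genes = env$genes)
    write.table(env$grn$table, out("grn_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    nEdges(env$grn$network)
  }, needed = !is.null(env$expr))

  runStage("egrn", function(s) {
    ext <- list()
    if (hasPath(cfg, "kinase"))
      ext <- c(ext, list(readNetwork(cfg$paths$kinase, "kinase")))
    if (hasPath(cfg, "signaling"))
      ext <- c(ext, list(readNetwork(cfg$paths$signaling, "signaling")))
    env$egrn <- largestComponent(mergeNetworks(env$grn$network, ext))
    writeNetwork(env$egrn, out("egrn_edges.tsv"))
    nEdges(env$egrn)
  }, needed = !is.null(env$grn))

  runStage("topology", function(s) {
    ts <- topologySummary(env$egrn, nRandom = cfg$nRandom, seed = s)
    df <- data.frame(avg_shortest_path = ts@avgShortestPath,
                     clustering_coefficient = ts@clusteringCoefficient,
                     avg_neighbors = ts@avgNeighbors,
                     z_aspl = ts@zAspl, z_clustering = ts@zClustering,
                     n_random = ts@nRandom, connected = ts@connected)
    write.table(df, out("topology.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    1L
  }, needed = !is.null(env$egrn))

  runStage("cc", function(s) {
    env$cc <- controlCentralityAll(env$egrn, seed = s)
    write.table(data.frame(node = names(ccValues(env$cc)),
                           cc = ccValues(env$cc),
                           normalized_cc = normalizedCc(env$cc)),
                out("control_centrality.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    env$cc@N
  }, needed = !is.null(env$egrn))

  runStage("hicc", function(s) {
    env$pathways <- readGmt(cfg$paths$pathways)
    env$hicc <- hiccPathways(env$cc, env$pathways, pCut = cfg$pCut,
                             minOverlap = cfg$minOverlap,
                             excludeCancer = cfg$excludeCancer)
    write.table(env$hicc, out("hicc_pathways.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sum(env$hicc$is_hicc)
  }, needed = !is.null(env$cc) && hasPath(cfg, "pathways"))

  runStage("enrich", function(s) {
    universe <- names(ccValues(env$cc))
    tested <- env$hicc[env$hicc$tested, ]
    sets <- env$pathways[tested$pathway]
    contrasts <- list()
    for (key in c("gold", "gwasDisease")) {
      if (!hasPath(cfg, key)) next
      dg <- setdiff(readGeneList(cfg$paths[[key]]), env$gwasSeed)
      enr <- pathwayEnrichment(sets, dg, universe, pCut = cfg$pCut)
      write.table(enr, out(paste0("enrichment_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      contrasts[[key]] <- hiccEnrichmentContrast(
        setNames(tested$is_hicc, tested$pathway),
        setNames(enr$enriched, enr$pathway))
    }
    jsonlite::write_json(
      lapply(contrasts, function(z)
        list(table = as.vector(z$table), odds_ratio = z$odds_ratio,
             p = z$p)),
      out("enrichment_contrasts.json"), auto_unbox = TRUE, digits = NA)
    length(contrasts)
  }, needed = !is.null(env$hicc) &&
       (hasPath(cfg, "gold") || hasPath(cfg, "gwasDisease")))

  runStage("eqtl", function(s) {
    geno <- readDosages(cfg$paths$genotypes)
    annot <- readGeneAnnotation(cfg$paths$annotation)
    hiccGenes <- unique(unlist(
      env$pathways[env$hicc$pathway[env$hicc$is_hicc]]))
    hiccGenes <- intersect(hiccGenes, names(ccValues(env$cc)))
    pairs <- cisPairs(hiccGenes, annot, geno, windowBp = cfg$windowBp)
    if (!nrow(pairs)) { env$eqtl <- NULL; return(0L) }
    res <- fitEqtl(env$expr, geno, pairs)
    res$perm_p <- NA_real_
    sig <- which(res$fdr_q < cfg$fdrCut)
    cd <- SummarizedExperiment::colData(env$expr)
    for (i in sig) {
      res$perm_p[i] <- permutationP(
        exprValues(env$expr)[res$gene[i], ],
        dosages(geno)[res$snp[i], ],
        data.frame(age = cd$age, sex = cd$sex),
        nPerm = cfg$nPerm, seed = s + i,
        legacyPermFloor = cfg$legacyPermFloor)
    }
    env$eqtl <- res
    write.table(res, out("eqtl.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    nrow(res)
  }, needed = !is.null(env$hicc) && hasPath(cfg, "genotypes") &&
       hasPath(cfg, "annotation"))

  runStage("steiner", function(s) {
    terms <- unique(env$eqtl$gene[env$eqtl$fdr_q < cfg$fdrCut])
    if (length(terms) < 2L) return(0L)
    sol <- kleinRaviSteiner(env$egrn, terms)
    roles <- data.frame(
      node = c(sol@terminals, sol@linkers),
      role = c(rep("terminal", length(sol@terminals)),
               rep("linker", length(sol@linkers))))
    write.table(roles, out("steiner_nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sol@edges, out("steiner_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    length(sol@linkers)
  }, needed = !is.null(env$eqtl) && nrow(env$eqtl) > 0)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
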