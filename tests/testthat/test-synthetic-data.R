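test_that("generators are bit-reproducible given the seed", {
  g1 <- generateRegulatoryNetwork(60, 3, seed = 5)
  g2 <- generateRegulatoryNetwork(60, 3, seed = 5)
  expect_identical(edgeTable(g1$network), edgeTable(g2$network))
  expect_identical(g1$truth$controller_genes, g2$truth$controller_genes)

  e1 <- simulateExpression(g1$network, g1$truth, nSamples = 20, seed = 9)
  e2 <- simulateExpression(g2$network, g2$truth, nSamples = 20, seed = 9)
  expect_identical(SummarizedExperiment::assay(e1),
                   SummarizedExperiment::assay(e2))

  expect_identical(generatePathways(g1$truth, seed = 3),
                   generatePathways(g1$truth, seed = 3))
  gg1 <- generateGenotypes(g1$truth, e1, seed = 4)
  gg2 <- generateGenotypes(g1$truth, e1, seed = 4)
  expect_identical(dosages(gg1$geno), dosages(gg2$geno))
})

test_that("zero cycle fraction yields a DAG; feedback creates cycles", {
  dag <- generateRegulatoryNetwork(80, 4, cycleFraction = 0, seed = 2)
  expect_true(igraph::is_dag(asIgraph(dag$network)))
  fb <- generateRegulatoryNetwork(80, 4, cycleFraction = 0.2, seed = 2)
  expect_false(igraph::is_dag(asIgraph(fb$network)))
  expect_error(generateRegulatoryNetwork(20, 4, outDegreeMean = 10),
               "genes-per-layer")
})

test_that("controller genes carry stochastically greater Cc", {
  gen <- generateRegulatoryNetwork(300, 5, seed = 19)
  cc <- ccValues(controlCentralityAll(gen$network, seed = 19))
  top <- cc[gen$truth$controller_genes]
  bottom <- cc[names(gen$truth$layers)[gen$truth$layers == 5]]
  expect_lt(groupRankSum(top, bottom, "greater")$p, 0.01)
})

test_that("SEM pairwise correlation matches the closed form", {
  net <- directedNetwork("A", "B")
  truth <- list(disease_genes = character(), layers = c(A = 1L, B = 2L))
  expr <- simulateExpression(net, truth, nSamples = 500, edgeWeight = 0.8,
                             seed = 27)
  x <- SummarizedExperiment::assay(expr)
  expect_equal(cor(x["A", ], x["B", ]), 0.8 / sqrt(1.64), tolerance = 0.13)
})

test_that("without a disease effect the DE stage stays at its nominal rate", {
  # genes are correlated through the SEM, so the positive rate of a single
  # replicate is overdispersed; the rate pooled over replicates is ~5%
  gen <- generateRegulatoryNetwork(300, 5, seed = 29)
  rate <- mean(vapply(1:10, function(r) {
    expr <- simulateExpression(gen$network, gen$truth, nSamples = 60,
                               diseaseEffect = 0, seed = 30 + r)
    mean(differentialRank(expr, "disease")$p < 0.05)
  }, numeric(1)))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("expression covariates mirror the cohort structure", {
  gen <- generateRegulatoryNetwork(60, 3, seed = 31)
  expr <- simulateExpression(gen$network, gen$truth, nSamples = 63,
                             seed = 32)
  cd <- SummarizedExperiment::colData(expr)
  expect_equal(sum(cd$disease), round(0.15 * 63))
  expect_gt(mean(cd$hba1c[cd$disease == 1]), mean(cd$hba1c[cd$disease == 0]))
  expect_true(all(cd$sex %in% 0:1))
})

test_that("pathway sets plant one controller pathway with unique names", {
  gen <- generateRegulatoryNetwork(120, 4, seed = 33)
  sets <- generatePathways(gen$truth, nDecoys = 8, seed = 34)
  expect_true(all(sets$CONTROLLER %in% gen$truth$controller_genes))
  expect_false(anyDuplicated(names(sets)) > 0)
  expect_true("CANCER_DECOY" %in% names(sets))
  expect_length(sets, 10)
})

test_that("planted SNPs are cis to their genes; others are uncorrelated", {
  gen <- generateRegulatoryNetwork(80, 4, seed = 35)
  expr <- simulateExpression(gen$network, gen$truth, nSamples = 100,
                             seed = 36)
  gg <- generateGenotypes(gen$truth, expr, nSnps = 50, nPlanted = 5,
                          seed = 37)
  pl <- gg$truth$planted_eqtl
  pairs <- cisPairs(pl$gene, gg$annot, gg$geno)
  expect_true(all(paste(pl$snp, pl$gene) %in%
                    paste(pairs$snp, pairs$gene)))
  # non-planted SNP-gene combinations: dosage-expression correlation ~ 0
  x <- SummarizedExperiment::assay(gg$expr)
  d <- dosages(gg$geno)
  withr::local_seed(38)
  rs <- replicate(200, {
    s <- sample(setdiff(rownames(d), pl$snp), 1)
    g <- sample(setdiff(rownames(x), pl$gene), 1)
    abs(cor(d[s, ], x[g, ]))
  })
  expect_gte(mean(rs < 0.2), 0.95)
})

test_that("the full synthetic bundle round-trips from disk", {
  d <- withr::local_tempdir()
  b <- writeSyntheticBundle(d, nGenes = 60, nLayers = 3, nSamples = 30,
                            nDecoys = 4, nSnps = 20, nPlanted = 3, seed = 8)
  expect_true(all(file.exists(file.path(d, c(
    "expression.tsv", "covariates.tsv", "prior_edges.tsv",
    "kinase_edges.tsv", "signaling_edges.tsv", "pathways.gmt",
    "construction_gwas_genes.txt", "gold_genes.txt",
    "gwas_disease_genes.txt", "genotypes.tsv", "gene_annotation.bed",
    "truth.json")))))
  expr <- readExpression(file.path(d, "expression.tsv"),
                         file.path(d, "covariates.tsv"))
  expect_equal(dim(SummarizedExperiment::assay(expr)), c(60L, 30L))
  geno <- readDosages(file.path(d, "genotypes.tsv"))
  expect_equal(nrow(dosages(geno)), 20L)
  annot <- readGeneAnnotation(file.path(d, "gene_annotation.bed"))
  expect_length(annot, 60)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$controller_genes),
                   sort(b$truth$controller_genes))
})

test_that("grn inference, Cc and HiCc recover the planted controller", {
  # features = the full gene panel (the variance filter is exercised in its
  # own tests; upstream regulators are the *lowest*-variance genes of a SEM,
  # so subsetting by variance would remove the very genes under study), and
  # the prior emulates a comprehensive directional TF-binding resource —
  # the hierarchy signal of MI-based inference rides on edge orientation,
  # which only the prior and the collider score provide
  gen <- generateRegulatoryNetwork(300, 5, seed = 43)
  expr <- simulateExpression(gen$network, gen$truth, nSamples = 60,
                             seed = 44)
  e <- gen$truth$edges
  prior <- directedNetwork(e$from, e$to, provenance = "prior")
  grn <- inferGrn(expr, prior,
                  cfg = grnConfig(nVariance = 300, nTotal = 300))
  lcc <- largestComponent(grn$network)
  cc <- controlCentralityAll(lcc, seed = 46)
  sets <- generatePathways(gen$truth, nDecoys = 20, seed = 47)
  h <- hiccPathways(cc, sets, minOverlap = 3)
  expect_true(h$is_hicc[h$pathway == "CONTROLLER"])
  dec <- h[grepl("^DECOY", h$pathway) & h$tested, ]
  expect_gte(mean(!dec$is_hicc), 0.8)
})
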