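makeExpr <- function(x, disease = NULL, hba1c = NULL) {
  n <- ncol(x)
  if (is.null(disease)) disease <- rep(c(0L, 1L), length.out = n)
  if (is.null(hba1c)) hba1c <- 5 + 2 * disease
  expressionData(x, data.frame(disease = disease, hba1c = hba1c,
                               age = seq(40, 70, length.out = n),
                               sex = rep(c(0L, 1L), length.out = n)))
}

test_that("feature selection fills variance, GWAS and DE slots", {
  withr::local_seed(1)
  x <- matrix(rnorm(10 * 40), 10, 40,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  x[1:3, ] <- x[1:3, ] * 10                   # variance winners
  x[8:10, 21:40] <- x[8:10, 21:40] + 3        # DE winners
  expr <- makeExpr(x, disease = rep(0:1, each = 20))
  sel <- selectFeatures(expr, cfg = grnConfig(nVariance = 3, nTotal = 5))
  expect_length(sel, 5)
  expect_true(all(c("g01", "g02", "g03") %in% sel))
  expect_true(sum(sprintf("g%02d", 8:10) %in% sel) >= 2)

  # a GWAS gene already selected by variance is counted once
  sel2 <- selectFeatures(expr, gwasGenes = "g01",
                         cfg = grnConfig(nVariance = 3, nTotal = 5))
  expect_length(sel2, 5)

  # invariant to gene order
  x2 <- x[rev(rownames(x)), ]
  expr2 <- makeExpr(x2, disease = rep(0:1, each = 20))
  expect_identical(sel,
                   selectFeatures(expr2,
                                  cfg = grnConfig(nVariance = 3, nTotal = 5)))
})

test_that("feature selection warns when the DE fill runs dry", {
  withr::local_seed(2)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), NULL))
  expr <- makeExpr(x)
  expect_warning(
    sel <- selectFeatures(expr, cfg = grnConfig(nVariance = 2, nTotal = 6,
                                                dePThreshold = 1e-12)),
    "shorter")
  expect_lt(length(sel), 6)
})

test_that("moderated t is near zero for equal means and finds real shifts", {
  withr::local_seed(3)
  x <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  x[1:50, 21:40] <- x[1:50, 21:40] + 3  # 3-sd shift, 20 vs 20
  flat <- matrix(rep(rowMeans(x[1:2, ]), each = 40), 2, 40, byrow = FALSE)
  expr <- makeExpr(x, disease = rep(0:1, each = 20))
  dr <- differentialRank(expr, "disease")
  expect_gte(mean(dr$p[1:50] < 0.05), 0.95)

  same <- makeExpr(rbind(g1 = rep(c(1, 2), 20)), disease = rep(0:1, each = 20))
  dr2 <- differentialRank(same, "disease")
  expect_lt(abs(dr2$t), 1e-8)
  expect_gt(dr2$p, 0.99)
})

test_that("moderated t holds its size under permuted labels", {
  withr::local_seed(4)
  x <- matrix(rnorm(2000 * 30), 2000, 30,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  expr <- makeExpr(x, disease = sample(rep(0:1, 15)))
  dr <- differentialRank(expr, "disease")
  expect_gt(mean(dr$p < 0.05), 0.03)
  expect_lt(mean(dr$p < 0.05), 0.07)
})

test_that("moderated-t ranking agrees with limma's moderated t", {
  skip_if_not_installed("limma")
  withr::local_seed(5)
  x <- matrix(rnorm(300 * 24), 300, 24,
              dimnames = list(sprintf("g%03d", 1:300), NULL))
  x[1:30, 13:24] <- x[1:30, 13:24] + 2
  grp <- rep(0:1, each = 12)
  expr <- makeExpr(x, disease = grp)
  ours <- differentialRank(expr, "disease")
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, grp)))
  # shrinkage targets differ slightly; the rankings must agree closely
  expect_gt(cor(abs(ours$t), abs(fit$t[, 2]), method = "spearman"), 0.98)
})

test_that("mutual information behaves like an MI estimator should", {
  withr::local_seed(6)
  x <- rnorm(9)
  expect_equal(mutualInformation(x, x, bins = 3), log(3))
  expect_equal(mutualInformation(x, rev(x)), mutualInformation(rev(x), x))
  expect_equal(mutualInformation(rep(1, 20), rnorm(20)), 0)
  u <- runif(10000); v <- runif(10000)
  expect_lt(mutualInformation(u, v), 0.01)
  for (k in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_gte(mutualInformation(a, b), 0)
  }
})

test_that("MRMR picks the informative parent first and penalizes redundancy", {
  withr::local_seed(7)
  n <- 300
  A <- rnorm(n)
  A2 <- A + rnorm(n, sd = 0.05)     # near-copy of A
  B <- rnorm(n)                     # independent, weaker signal
  t <- A + 0.6 * B + rnorm(n, sd = 0.3)
  x <- rbind(A = A, A2 = A2, B = B, t = t, noise = rnorm(n))
  expr <- makeExpr(x)
  par <- mrmrParents(expr, "t", c("A", "A2", "B", "noise"),
                     grnConfig(maxParents = 2))
  expect_equal(par[1], "A")
  expect_equal(par[2], "B")   # A2 is redundant with A and loses to B
  expect_lte(length(mrmrParents(expr, "t", c("A", "A2", "B", "noise"),
                                grnConfig(maxParents = 3))), 3)
  expect_identical(mrmrParents(expr, "t", character()), character())
})

test_that("the causality score recognizes colliders and is bounded", {
  withr::local_seed(8)
  n <- 200
  collider <- 0L; chain <- 0L
  for (r in 1:100) {
    xx <- rnorm(n); zz <- rnorm(n)
    tt <- xx + zz + rnorm(n, sd = 0.5)
    expr <- makeExpr(rbind(x = xx, z = zz, t = tt))
    s <- causalityScore(expr, "t", "x", "z")
    expect_gte(s, -1); expect_lte(s, 1)
    collider <- collider + (s > 0)

    x2 <- rnorm(n); z2 <- x2 + rnorm(n, sd = 0.5)
    t2 <- z2 + rnorm(n, sd = 0.5)
    expr2 <- makeExpr(rbind(x = x2, z = z2, t = t2))
    chain <- chain + (causalityScore(expr2, "t", "x", "z") <= 0)
  }
  expect_gte(collider, 90)
  expect_gte(chain, 80)
  expect_equal(causalityScore(makeExpr(matrix(rnorm(20), 2, 10,
                                              dimnames = list(c("a", "b")))),
                              "b", "a", character()), 0)
})

test_that("prior combination arithmetic and retention rule", {
  cfg <- grnConfig(priorWeight = 0.75)
  prior <- directedNetwork("P", "T", provenance = "prior")
  scored <- data.frame(parent = c("D", "E"), target = c("T", "T"),
                       causality_score = c(-0.5, 0.4))
  res <- combineWithPrior(scored, prior, cfg,
                          geneUniverse = c("P", "T", "D", "E"))
  tab <- res$table
  expect_equal(tab$combined_score[tab$parent == "P"], 0.25)  # prior only
  expect_false("D" %in% tab$parent)                          # -0.375 dropped
  expect_equal(tab$combined_score[tab$parent == "E"], 0.3)   # 0.75*0.4
  scored2 <- data.frame(parent = "P", target = "T", causality_score = 0.4)
  res2 <- combineWithPrior(scored2, prior, cfg)
  expect_equal(res2$table$combined_score, 0.55)              # data + prior
})

test_that("planted single parents are recovered on a two-layer SEM", {
  withr::local_seed(9)
  gen <- generateRegulatoryNetwork(40, 2, outDegreeMean = 2,
                                   cycleFraction = 0, seed = 101)
  expr <- simulateExpression(gen$network, gen$truth, nSamples = 200,
                             seed = 102)
  e <- gen$truth$edges
  singles <- names(which(table(e$to) == 1))
  hits <- vapply(singles, function(tg) {
    first <- mrmrParents(expr, tg, setdiff(nodeIds(gen$network), tg),
                         grnConfig(maxParents = 1))
    identical(first[1], e$from[e$to == tg])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
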