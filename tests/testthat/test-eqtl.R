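tinyGeno <- function(pos, chr = "1", nSamples = 6) {
  snp <- sprintf("s%02d", seq_along(pos))
  d <- matrix(rep(0:2, length.out = length(pos) * nSamples),
              length(pos), nSamples,
              dimnames = list(snp, sprintf("S%03d", seq_len(nSamples))))
  genotypeMatrix(d, data.frame(snp = snp, chr = chr, pos = pos))
}

test_that("cis pairing respects the inclusive 250 kb boundary", {
  annot <- geneAnnotation(data.frame(gene = "G", chr = "1",
                                     start = 1000, end = 2000))
  geno <- tinyGeno(c(252000, 252001, 1500, 749999, 750001))
  pr <- cisPairs("G", annot, geno, windowBp = 250000)
  expect_setequal(pr$snp, c("s01", "s03")) # 2000+250000 inclusive; body SNP
  # lower bound: start - window = -249000 -> everything left of gene pairs
  pr2 <- cisPairs("G", annot, tinyGeno(1), windowBp = 250000)
  expect_equal(nrow(pr2), 1L)
})

test_that("cis pairing is chromosome-aware and skips unannotated genes", {
  annot <- geneAnnotation(data.frame(gene = "G", chr = "1",
                                     start = 1000, end = 2000))
  geno <- tinyGeno(1500, chr = "2")
  expect_equal(nrow(cisPairs("G", annot, geno)), 0L)
  expect_warning(pr <- cisPairs(c("G", "MISSING"), annot, tinyGeno(1500)),
                 "missing annotation")
  expect_equal(pr$gene, "G")
})

test_that("eQTL regression recovers planted effects and adjusts covariates", {
  withr::local_seed(21)
  n <- 100
  betas <- numeric(40)
  for (r in 1:40) {
    sim <- simulateEqtlPair(n, beta = 1)
    x <- matrix(sim$y, 1, n,
                dimnames = list("Y", sprintf("S%03d", 1:n)))
    expr <- expressionData(
      x, data.frame(sample = sprintf("S%03d", 1:n), disease = 0L,
                    hba1c = 5.5, age = sim$covar$age, sex = sim$covar$sex))
    g <- matrix(sim$g, 1, n,
                dimnames = list("SNP", sprintf("S%03d", 1:n)))
    geno <- genotypeMatrix(g, data.frame(snp = "SNP", chr = "1", pos = 500))
    res <- fitEqtl(expr, geno, data.frame(snp = "SNP", gene = "Y"))
    betas[r] <- res$beta
  }
  expect_lt(abs(mean(betas) - 1), 0.15)

  # age-driven expression with no genotype effect stays null
  hits <- 0L
  for (r in 1:200) {
    sim <- simulateEqtlPair(n, beta = 0)
    y <- 0.1 * sim$covar$age + rnorm(n)
    expr <- expressionData(
      matrix(y, 1, n, dimnames = list("Y", sprintf("S%03d", 1:n))),
      data.frame(sample = sprintf("S%03d", 1:n), disease = 0L,
                 hba1c = 5.5, age = sim$covar$age, sex = sim$covar$sex))
    g <- matrix(sim$g, 1, n, dimnames = list("SNP", sprintf("S%03d", 1:n)))
    geno <- genotypeMatrix(g, data.frame(snp = "SNP", chr = "1", pos = 500))
    res <- fitEqtl(expr, geno, data.frame(snp = "SNP", gene = "Y"))
    hits <- hits + (res$p < 0.05)
  }
  expect_gt(hits / 200, 0.015); expect_lt(hits / 200, 0.1)
})

test_that("monomorphic SNPs are skipped and recorded", {
  withr::local_seed(22)
  n <- 30
  x <- rbind(Y = rnorm(n))
  colnames(x) <- sprintf("S%03d", 1:n)
  expr <- expressionData(x, data.frame(sample = colnames(x), disease = 0L,
                                       hba1c = 5.5, age = rnorm(n, 50, 5),
                                       sex = rep(0:1, 15)))
  d <- rbind(mono = rep(1, n), poly = rbinom(n, 2, 0.4))
  colnames(d) <- colnames(x)
  geno <- genotypeMatrix(d, data.frame(snp = c("mono", "poly"), chr = "1",
                                       pos = c(100, 200)))
  res <- fitEqtl(expr, geno, data.frame(snp = c("mono", "poly"),
                                        gene = c("Y", "Y")))
  expect_equal(res$snp, "poly")
  expect_equal(attr(res, "skipped")$snp, "mono")
  expect_true(all(res$fdr_q >= res$p))
})

test_that("permutation p-values honor the seed, the null and the floor", {
  withr::local_seed(23)
  sim <- simulateEqtlPair(80, beta = 2)
  p1 <- permutationP(sim$y, sim$g, sim$covar, nPerm = 500, seed = 9)
  p2 <- permutationP(sim$y, sim$g, sim$covar, nPerm = 500, seed = 9)
  expect_identical(p1, p2)
  # overwhelming signal: no permutation reaches it -> legacy floor 1/nPerm
  expect_equal(p1, 1 / 500)
  expect_equal(permutationP(sim$y, sim$g, sim$covar, nPerm = 500, seed = 9,
                            legacyPermFloor = FALSE), 1 / 501)
  # null pair: p near 1-ish, and never below the floor
  nullp <- permutationP(rnorm(80), sim$g, sim$covar, nPerm = 200, seed = 2)
  expect_gte(nullp, 1 / 201)
  expect_gt(nullp, 0.05)
})

test_that("permutation and asymptotic p-values rank together", {
  withr::local_seed(24)
  n <- 60
  pp <- aa <- numeric(40)
  for (r in 1:40) {
    sim <- simulateEqtlPair(n, beta = runif(1, 0, 0.8))
    X <- cbind(1, sim$g, as.matrix(sim$covar))
    fit <- lm(sim$y ~ sim$g + sim$covar$age + sim$covar$sex)
    aa[r] <- summary(fit)$coefficients[2, 4]
    pp[r] <- permutationP(sim$y, sim$g, sim$covar, nPerm = 400, seed = r,
                          legacyPermFloor = FALSE)
  }
  expect_gt(cor(rank(pp), rank(aa)), 0.95)
})

test_that("the rank-sum utility matches hand-enumerated tails", {
  rs <- groupRankSum(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(rs$p, 1 / 20)
  expect_equal(groupRankSum(c(1, 2, 3), c(4, 5, 6), "less")$p, 1 / 20)
  both <- groupRankSum(rep(1:5, 2), rep(1:5, 2))
  expect_gte(both$p, 0.9)
})

test_that("dosage TSV and VCF readers agree on the same genotypes", {
  withr::local_seed(25)
  d <- matrix(rbinom(12, 2, 0.5), 3, 4,
              dimnames = list(c("rs1", "rs2", "rs3"), sprintf("S%d", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp = rownames(d), chr = "1",
                         pos = c(100, 200, 300), d),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  geno <- readDosages(f)
  expect_equal(unname(dosages(geno)), unname(d))

  gtOf <- function(x) c("0/0", "0/1", "1/1")[x + 1]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sprintf("S%d", 1:4)),
                     collapse = "\t"),
               vapply(1:3, function(i)
                 paste(c("1", c(100, 200, 300)[i], rownames(d)[i], "A", "G",
                         ".", "PASS", ".", "GT", gtOf(d[i, ])),
                       collapse = "\t"), character(1))), vcf)
  genoV <- readVcfDosages(vcf)
  expect_equal(unname(dosages(genoV)), unname(d))
  expect_equal(snpPositions(genoV)$pos, c(100, 200, 300))
})
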