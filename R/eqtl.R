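#' Gene annotation as genomic ranges
#'
#' @param df data.frame with columns `gene`, `chr`, `start`, `end`
#'   (1-based, inclusive).
#' @return a [GenomicRanges::GRanges] named by gene id.
#' @export
geneAnnotation <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("gene", "chr", "start", "end") %in% names(df)),
            all(df$start <= df$end))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chr),
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  names(gr) <- as.character(df$gene)
  gr
}

#' Read a BED-like gene annotation (chr, start, end, gene; 0-based starts)
#' @param path file path.
#' @return a [GenomicRanges::GRanges] named by gene id.
#' @export
readGeneAnnotation <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chr", "start", "end", "gene"))
  df$start <- df$start + 1L # BED half-open to 1-based inclusive
  geneAnnotation(df)
}

#' Read a dosage TSV (snp, chr, pos, then one column per sample)
#' @param path file path.
#' @return a [GenotypeMatrix-class].
#' @export
readDosages <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  stopifnot(all(c("snp", "chr", "pos") %in% names(df)))
  d <- as.matrix(df[, setdiff(names(df), c("snp", "chr", "pos")),
                    drop = FALSE])
  rownames(d) <- df$snp
  genotypeMatrix(d, df[, c("snp", "chr", "pos")])
}

#' Minimal VCF-to-dosage reader
#'
#' Convenience reader converting the GT field of a VCF into 0/1/2 alternate
#' allele dosages via the vcfR package; missing genotypes become NA.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [GenotypeMatrix-class].
#' @export
readVcfDosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) |
                                                       ids == "."]
  rownames(dos) <- ids
  genotypeMatrix(dos, data.frame(snp = ids, chr = fix[, "CHROM"],
                                 pos = as.integer(fix[, "POS"])))
}

#' Candidate cis SNP-gene pairs
#'
#' Pairs every SNP lying within `windowBp` of a gene body (inclusive bounds:
#' positions in `[start - window, end + window]` on the same chromosome)
#' with that gene. Genes missing from the annotation are skipped with a
#' warning.
#'
#' @param genes character vector of gene ids to map.
#' @param annot a [GenomicRanges::GRanges] from [geneAnnotation()].
#' @param geno a [GenotypeMatrix-class].
#' @param windowBp cis window in base pairs (default 250000).
#' @return data.frame with columns `snp`, `gene`.
#' @export
cisPairs <- function(genes, annot, geno, windowBp = 250000L) {
  stopifnot(windowBp >= 0)
  miss <- setdiff(genes, names(annot))
  if (length(miss))
    warning(length(miss), " gene(s) missing annotation, skipped: ",
            paste(head(miss, 5), collapse = ", "))
  genes <- intersect(genes, names(annot))
  if (!length(genes)) return(data.frame(snp = character(),
                                        gene = character()))
  gr <- annot[genes]
  ext <- gr
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(gr) - windowBp)
  GenomicRanges::end(ext) <- GenomicRanges::end(gr) + windowBp
  sp <- snpPositions(geno)
  snps <- GenomicRanges::GRanges(seqnames = sp$chr,
                                 ranges = IRanges::IRanges(sp$pos, sp$pos))
  ov <- suppressWarnings( # disjoint seqlevels across inputs are expected
    GenomicRanges::findOverlaps(snps, ext, ignore.strand = TRUE))
  out <- data.frame(snp = sp$snp[S4Vectors::queryHits(ov)],
                    gene = names(ext)[S4Vectors::subjectHits(ov)])
  out[order(out$gene, out$snp), , drop = FALSE]
}

# residualize columns of y on covariate design (with intercept)
residualize <- function(y, covar) {
  X <- cbind(1, covar)
  qr.resid(qr(X), y)
}

#' Fit cis-eQTL linear models
#'
#' For every SNP-gene pair fits ordinary least squares
#' `expression ~ intercept + dosage + age + sex` and reports the dosage
#' coefficient, its t statistic and two-sided p-value, with
#' Benjamini-Hochberg q-values computed jointly across all tested pairs.
#' Monomorphic SNPs (zero dosage variance) are skipped and recorded.
#'
#' @param expr a `SummarizedExperiment` with `age` and `sex` covariates.
#' @param geno a [GenotypeMatrix-class] whose samples match `expr`.
#' @param pairs data.frame (`snp`, `gene`) from [cisPairs()].
#' @return data.frame with `snp`, `gene`, `beta`, `t_stat`, `p`, `fdr_q`,
#'   plus attribute `"skipped"` listing monomorphic pairs.
#' @export
fitEqtl <- function(expr, geno, pairs) {
  x <- exprValues(expr)
  d <- dosages(geno)
  stopifnot(identical(colnames(x), colnames(d)))
  cd <- SummarizedExperiment::colData(expr)
  covar <- cbind(age = cd$age, sex = cd$sex)
  n <- ncol(x)
  npar <- 4L
  if (n < npar + 5L) stop("need at least ", npar + 5L, " samples")
  keepRow <- logical(nrow(pairs))
  beta <- tstat <- pval <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- d[pairs$snp[i], ]
    if (var(g) == 0) next
    X <- cbind(1, g, covar)
    fit <- lm.fit(X, x[pairs$gene[i], ])
    rss <- sum(fit$residuals^2)
    dfres <- n - npar
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / dfres * XtXinv[2, 2])
    beta[i] <- fit$coefficients[2]
    tstat[i] <- beta[i] / se
    pval[i] <- 2 * pt(-abs(tstat[i]), dfres)
    keepRow[i] <- TRUE
  }
  out <- data.frame(snp = pairs$snp, gene = pairs$gene, beta = beta,
                    t_stat = tstat, p = pval)[keepRow, , drop = FALSE]
  out$fdr_q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- pairs[!keepRow, , drop = FALSE]
  out
}

#' Permutation p-value for one SNP-gene pair
#'
#' Residualizes both expression and dosage on the covariates (intercept, age,
#' sex), then permutes the residualized expression across samples and
#' recomputes the dosage t statistic each time:
#' `p = (1 + #permuted |t| >= observed |t|) / (nPerm + 1)`. Under the legacy
#' floor convention (default), a pair whose observed statistic exceeds every
#' permuted one reports `1 / nPerm` instead of the add-one floor — the
#' convention behind a printed floor of 1.00E-04 at 10,000 permutations.
#'
#' @param exprRow numeric expression vector (one gene across samples).
#' @param genoRow numeric dosage vector across the same samples.
#' @param covariates data.frame or matrix with columns `age` and `sex`.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed; deterministic given the seed.
#' @param legacyPermFloor report `1/nPerm` when no permutation reaches the
#'   observed statistic (default TRUE).
#' @return the permutation p-value.
#' @export
permutationP <- function(exprRow, genoRow, covariates, nPerm = 10000L,
                         seed = 1L, legacyPermFloor = TRUE) {
  stopifnot(nPerm >= 1)
  covar <- as.matrix(as.data.frame(covariates)[, c("age", "sex")])
  ry <- residualize(exprRow, covar)
  rg <- residualize(genoRow, covar)
  n <- length(ry)
  dfres <- n - 4L # intercept + dosage + age + sex
  tOf <- function(y) {
    b <- sum(rg * y) / sum(rg^2)
    res <- y - b * rg
    se <- sqrt(sum(res^2) / dfres / sum(rg^2))
    b / se
  }
  tObs <- abs(tOf(ry))
  withr::local_seed(seed)
  exceed <- 0L
  for (k in seq_len(nPerm)) {
    if (abs(tOf(ry[sample.int(n)])) >= tObs) exceed <- exceed + 1L
  }
  if (exceed == 0L && legacyPermFloor) 1 / nPerm
  else (1 + exceed) / (nPerm + 1)
}

#' Two-group rank-sum test
#'
#' Mann-Whitney U with normal approximation and tie correction; exact
#' enumeration when the smaller group has at most 8 untied observations.
#'
#' @param valuesA,valuesB numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (A greater) or
#'   `"less"`.
#' @return list with `U` (statistic for group A) and `p`.
#' @export
groupRankSum <- function(valuesA, valuesB,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(valuesA) > 0, length(valuesB) > 0)
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0
  exact <- !ties && min(length(valuesA), length(valuesB)) <= 8
  wt <- suppressWarnings(wilcox.test(valuesA, valuesB,
                                     alternative = alternative,
                                     exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
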