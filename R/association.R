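# SNP QC and the two-step pattern-SNP association scan: one-way 2-df ANOVA
# of patterns on genotype classes, per-gene ANOVA for suggestive SNPs, and
# hypergeometric module enrichment at the study-wise Bonferroni threshold;
# plus mediation adjustment and pattern-phenotype correlation.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the minor-allele
#' count: the two-sided p-value sums the probabilities of all heterozygote
#' counts no more likely than the observed one.
#'
#' @param nHomRef,nHet,nHomAlt genotype class counts.
#' @return p-value in [0, 1].
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  n <- nHomRef + nHet + nHomAlt
  if (n == 0) return(1)
  nA <- 2 * nHomAlt + nHet          # minor-ish allele count
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    homAlt <- (nA - h) / 2
    homRef <- n - h - homAlt
    h * log(2) + lfactorial(n) - lfactorial(homRef) - lfactorial(h) -
      lfactorial(homAlt)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hs == nHet]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' SNP quality control
#'
#' Drops SNPs failing any of: minor allele frequency >= `mafMin`, exact
#' Hardy-Weinberg test p >= `hweAlpha` (computed on complete genotypes), and
#' call rate >= `callMin`.
#'
#' @param g \linkS4class{GenotypeData}.
#' @param mafMin,hweAlpha,callMin thresholds (defaults 0.01, 1e-4, 0.95).
#' @return list with `genotypes` (filtered \linkS4class{GenotypeData}) and
#'   `report` (per-SNP data.frame: snp, maf, hweP, callRate, keep).
#' @export
snpQC <- function(g, mafMin = 0.01, hweAlpha = 1e-4, callMin = 0.95) {
  d <- doseMatrix(g)
  maf <- minorAlleleFreq(g)
  cr <- callRate(g)
  hweP <- apply(d, 1, function(row) {
    row <- row[!is.na(row)]
    hweExactTest(sum(row == 0), sum(row == 1), sum(row == 2))
  })
  keep <- maf >= mafMin & hweP >= hweAlpha & cr >= callMin
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("all SNPs dropped by QC")
  report <- data.frame(snp = rownames(d), maf = maf, hweP = hweP,
                       callRate = cr, keep = keep, row.names = NULL)
  list(genotypes = g[keep, ], report = report)
}

#' One-way ANOVA of a trait on genotype classes (up to 2 df)
#'
#' Fixed-effects ANOVA with genotype as a categorical factor after pairwise
#' removal of missing data; the between df is the number of genotype classes
#' present minus one.
#'
#' @param y numeric trait over samples.
#' @param geno doses in \{0, 1, 2\} (NA allowed).
#' @return one-row data.frame: F, df1, df2, p, r2 (SS_between / SS_total),
#'   n, status (`"ok"`, `"untestable"` or `"degenerate"`).
#' @export
anova2df <- function(y, geno) {
  use <- !is.na(y) & !is.na(geno)
  y <- y[use]; geno <- geno[use]
  n <- length(y)
  cls <- sort(unique(geno))
  C <- length(cls)
  if (n == 0 || C < 2)
    return(data.frame(F = NA_real_, df1 = 0L, df2 = n - C, p = 1,
                      r2 = 0, n = n, status = "untestable"))
  m <- mean(y)
  sst <- sum((y - m)^2)
  gm <- vapply(cls, function(cl) mean(y[geno == cl]), numeric(1))
  nc <- vapply(cls, function(cl) sum(geno == cl), numeric(1))
  ssb <- sum(nc * (gm - m)^2)
  ssw <- sst - ssb
  df1 <- C - 1L
  df2 <- n - C
  if (sst == 0)
    return(data.frame(F = NA_real_, df1 = df1, df2 = df2, p = 1, r2 = 0,
                      n = n, status = "untestable"))
  if (ssw <= sst * 1e-14 && ssb > 0)
    return(data.frame(F = Inf, df1 = df1, df2 = df2, p = 0, r2 = 1,
                      n = n, status = "degenerate"))
  Fv <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  data.frame(F = Fv, df1 = df1, df2 = df2, p = p, r2 = ssb / sst, n = n,
             status = "ok")
}

#' Scan targets (patterns or gene expressions) against all SNPs
#'
#' Tests every target x SNP pair by [anova2df()] (vectorized over targets)
#' and returns the records with p below `pMax`. Target and genotype sample
#' ids must match.
#'
#' @param targets numeric matrix, targets x samples, with rownames (pattern
#'   or gene ids) and colnames (sample ids).
#' @param g \linkS4class{GenotypeData} on the same samples.
#' @param pMax p-value ceiling for returned records (default 1e-7).
#' @return data.frame: snp, target, F, df1, df2, p, r2, n; attribute
#'   `nTested` holds the number of pairs tested.
#' @export
scanAssociations <- function(targets, g, pMax = 1e-7) {
  targets <- as.matrix(targets)
  d <- doseMatrix(g)
  if (is.null(colnames(targets)) || is.null(colnames(d)) ||
      !identical(colnames(targets), colnames(d))) {
    off <- union(setdiff(colnames(targets), colnames(d)),
                 setdiff(colnames(d), colnames(targets)))
    stop("sample ids of targets and genotypes do not match: ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  }
  nT <- nrow(targets)
  hits <- vector("list", nrow(d))
  for (s in seq_len(nrow(d))) {
    geno <- d[s, ]
    use <- !is.na(geno)
    y <- targets[, use, drop = FALSE]
    gs <- geno[use]
    cls <- sort(unique(gs))
    C <- length(cls)
    n <- sum(use)
    if (C < 2 || n - C < 1) next
    Z <- outer(gs, cls, `==`) + 0          # n x C indicators
    nc <- colSums(Z)
    m <- rowMeans(y)
    sst <- rowSums((y - m)^2)
    gmeans <- sweep(y %*% Z, 2, nc, `/`)   # nT x C
    ssb <- rowSums(sweep((gmeans - m)^2, 2, nc, `*`))
    ssw <- pmax(sst - ssb, 0)
    df1 <- C - 1
    df2 <- n - C
    Fv <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p[sst == 0] <- 1
    sel <- which(p < pMax)
    if (length(sel))
      hits[[s]] <- data.frame(snp = rownames(d)[s],
                              target = rownames(targets)[sel],
                              F = Fv[sel], df1 = df1, df2 = df2,
                              p = p[sel], r2 = (ssb / sst)[sel], n = n,
                              row.names = NULL)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(snp = character(), target = character(), F = numeric(),
                      df1 = integer(), df2 = integer(), p = numeric(),
                      r2 = numeric(), n = integer())
  attr(out, "nTested") <- nT * nrow(d)
  out
}

#' Study-wise Bonferroni threshold for module enrichment
#'
#' `alpha / (nModules * nSnps)` with the mantissa truncated to three
#' significant digits for reporting; the exact value is kept in the
#' `"exact"` attribute.
#'
#' @param nModules,nSnps positive counts.
#' @param alpha family-wise alpha (default 0.05).
#' @return the truncated threshold.
#' @export
studyWiseThreshold <- function(nModules, nSnps, alpha = 0.05) {
  stopIfNot(nModules > 0 && nSnps > 0, "counts must be positive")
  thr <- alpha / (as.numeric(nModules) * as.numeric(nSnps))
  e <- floor(log10(thr))
  trunc3 <- floor(thr / 10^e * 100) / 100 * 10^e
  structure(trunc3, exact = thr)
}

#' Module enrichment in expression traits associated to a SNP (step 2)
#'
#' Upper-tail hypergeometric test of whether the module is enriched in genes
#' individually associated to the SNP, by reference to the whole set of
#' analyzed expression traits.
#'
#' @param m \linkS4class{GeneModule} (genes within `universe`).
#' @param snpGeneHits gene ids associated to the SNP (e.g. at p < 1e-5).
#' @param universe all analyzed gene ids.
#' @param threshold significance threshold (see [studyWiseThreshold()]).
#' @return one-row data.frame: N, kAssoc, nModule, kHit, p, threshold, pass.
#' @export
moduleEnrichmentStep <- function(m, snpGeneHits, universe, threshold) {
  stopIfNot(length(universe) > 0, "empty universe")
  genes <- moduleGenes(m)
  stopIfNot(all(genes %in% universe), "module genes outside the universe")
  hits <- intersect(snpGeneHits, universe)
  N <- length(universe)
  K <- length(hits)
  n <- length(genes)
  k <- length(intersect(hits, genes))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(N = N, kAssoc = K, nModule = n, kHit = k, p = p,
             threshold = as.numeric(threshold), pass = p < threshold)
}

# Residualize a vector or the columns of a matrix on covariates (with
# intercept); rank-deficient designs fall back to the least-norm fit.
.residualize <- function(v, covariates) {
  X <- cbind(1, covariates)
  fit <- stats::lm.fit(X, v)
  as.matrix(fit$residuals)
}

#' Mediation adjustment of a trans association by cis transcripts
#'
#' Compares the genotype-class R2 on a trans expression trait before and
#' after residualizing both the trait and the genotype-class indicators on
#' the mediator expressions (partial R2). A trans effect fully mediated by
#' the cis transcripts drops to ~0 after adjustment.
#'
#' @param transExpr numeric trait over samples.
#' @param geno doses in \{0, 1, 2\}.
#' @param mediators numeric matrix (samples x mediators) or list of numeric
#'   vectors; empty means no adjustment.
#' @return list with `r2Unadjusted`, `r2Adjusted` and `n`.
#' @export
mediationAdjust <- function(transExpr, geno, mediators = NULL) {
  if (is.list(mediators)) mediators <- do.call(cbind, mediators)
  rec <- anova2df(transExpr, geno)
  if (is.null(mediators) || length(mediators) == 0)
    return(list(r2Unadjusted = rec$r2, r2Adjusted = rec$r2, n = rec$n))
  mediators <- as.matrix(mediators)
  use <- !is.na(transExpr) & !is.na(geno) &
    stats::complete.cases(mediators)
  y <- transExpr[use]; gv <- geno[use]; M <- mediators[use, , drop = FALSE]
  rec <- anova2df(y, gv)
  cls <- sort(unique(gv))
  if (length(cls) < 2)
    return(list(r2Unadjusted = rec$r2, r2Adjusted = 0, n = rec$n))
  Z <- outer(gv, cls[-1], `==`) + 0
  if (qr(cbind(1, M))$rank < ncol(M) + 1)
    warning("collinear mediators; least-norm fit used")
  ry <- .residualize(y, M)
  rZ <- .residualize(Z, M)
  fit <- stats::lm.fit(cbind(1, rZ), ry)
  ssTot <- sum((ry - mean(ry))^2)
  ssRes <- sum(fit$residuals^2)
  r2a <- if (ssTot > 0) max(0, 1 - ssRes / ssTot) else 0
  list(r2Unadjusted = rec$r2, r2Adjusted = r2a, n = rec$n)
}

#' Correlation of a pattern with a phenotype
#'
#' Pearson correlation with the two-sided p-value from the t transform;
#' missing phenotype values are dropped pairwise.
#'
#' @param aRow pattern activations over samples.
#' @param phenotype numeric phenotype over the same samples.
#' @return list with `r`, `p` and `n`.
#' @export
patternPhenotypeCorr <- function(aRow, phenotype) {
  use <- !is.na(aRow) & !is.na(phenotype)
  stopIfNot(sum(use) >= 3, "need at least 3 complete pairs")
  x <- aRow[use]; y <- phenotype[use]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(use))
}
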