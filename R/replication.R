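# Module-level replication in an independent dataset: per-gene association
# p-values of the module's genes with the lead SNP (or a proxy), combined by
# the two replication criteria.

#' Per-gene replication p-values for a module
#'
#' Tests each module gene measurable in the replication expression data
#' against one SNP by [anova2df()], optionally residualizing the expression
#' on a covariate matrix first (e.g. age, sex, centre).
#'
#' @param x \linkS4class{ExpressionData} of the replication study.
#' @param g \linkS4class{GenotypeData} of the replication study (same
#'   samples).
#' @param snpId SNP (row) id in `g`; a proxy SNP is simply whatever id the
#'   caller supplies.
#' @param genes module gene ids; only those measured in `x` are tested.
#' @param covariates optional samples x covariates numeric matrix.
#' @return named numeric vector of p-values (one per measurable gene).
#' @export
replicationPvalues <- function(x, g, snpId, genes, covariates = NULL) {
  v <- exprValues(x)
  d <- doseMatrix(g)
  stopIfNot(snpId %in% rownames(d), "SNP not present in replication data")
  stopIfNot(identical(colnames(v), colnames(d)),
            "replication expression and genotypes must share samples")
  geno <- d[snpId, ]
  genes <- intersect(genes, rownames(v))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    vg <- t(.residualize(t(v[genes, , drop = FALSE]), covariates))
  } else {
    vg <- v[genes, , drop = FALSE]
  }
  vapply(genes, function(gene) anova2df(vg[gene, ], geno)$p, numeric(1))
}

#' Decide module-level replication from per-gene p-values
#'
#' A module's association with a SNP replicates when both criteria hold:
#' (1) at least two genes are associated at 0.05 after Bonferroni correction
#' for the number of genes present in the module (the full module size, not
#' the measurable count); (2) the number of genes associated at the nominal
#' 0.05 level is significantly higher than 5%, by a one-sided exact binomial
#' test at 0.05.
#'
#' @param genePvalues numeric p-values of the module genes measurable in the
#'   replication data.
#' @param moduleSize total number of genes in the module.
#' @param alpha nominal level (default 0.05).
#' @param nullRate chance association rate for criterion 2 (default 0.05).
#' @param moduleId,snpId optional labels carried into the output.
#' @return one-row data.frame: moduleId, snpId, nGenesTested,
#'   nBonferroniHits, nNominalHits, binomialP, criterion1, criterion2,
#'   replicated, untestable.
#' @export
replicateModule <- function(genePvalues, moduleSize, alpha = 0.05,
                            nullRate = 0.05, moduleId = NA_character_,
                            snpId = NA_character_) {
  stopIfNot(moduleSize >= 1, "module size must be at least 1")
  genePvalues <- genePvalues[!is.na(genePvalues)]
  nTested <- length(genePvalues)
  if (nTested == 0)
    return(data.frame(moduleId = moduleId, snpId = snpId, nGenesTested = 0L,
                      nBonferroniHits = 0L, nNominalHits = 0L,
                      binomialP = NA_real_, criterion1 = FALSE,
                      criterion2 = FALSE, replicated = FALSE,
                      untestable = TRUE))
  nBonf <- sum(genePvalues < alpha / moduleSize)
  nNom <- sum(genePvalues < alpha)
  # one-sided exact binomial tail P(X >= nNom; nTested, nullRate)
  binP <- stats::pbinom(nNom - 1, nTested, nullRate, lower.tail = FALSE)
  c1 <- nBonf >= 2
  c2 <- binP < alpha
  data.frame(moduleId = moduleId, snpId = snpId, nGenesTested = nTested,
             nBonferroniHits = nBonf, nNominalHits = nNom, binomialP = binP,
             criterion1 = c1, criterion2 = c2, replicated = c1 && c2,
             untestable = FALSE)
}
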