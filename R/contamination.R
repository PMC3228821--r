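# Cell-type contamination surrogates: per-sample mean expression of genes
# specific to each non-target cell type, and post-hoc re-testing of
# SNP-pattern associations with the surrogates as covariates.

#' ContaminationSurrogates: per-sample surrogate variables of cell admixture
#'
#' @slot values samples x cell-types matrix.
#' @slot cellTypes character labels (column order).
#' @slot geneLists per-type gene ids actually used.
#' @export
setClass("ContaminationSurrogates",
  slots = c(values = "matrix", cellTypes = "character", geneLists = "list")
)
setValidity("ContaminationSurrogates", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@cellTypes))
    msg <- c(msg, "one column per cell type required")
  if (length(object@geneLists) != length(object@cellTypes))
    msg <- c(msg, "one gene list per cell type required")
  if (any(vapply(object@geneLists, length, integer(1)) < 1))
    msg <- c(msg, "each surrogate needs at least one gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContaminationSurrogates", function(object) {
  cat(sprintf("ContaminationSurrogates: %d samples x %d cell types (%s)\n",
              nrow(object@values), length(object@cellTypes),
              paste(utils::head(object@cellTypes, 7), collapse = ", ")))
})

#' Derive cell-specific gene lists from reference expression profiles
#'
#' A gene is specific to a lineage when its mean expression there exceeds
#' twice its maximum mean in every other lineage (fold change > 2, strict);
#' a gene can be specific to at most one lineage.
#'
#' @param reference genes x cell-types matrix of linear-scale mean
#'   expressions, with gene rownames and cell-type colnames.
#' @param foldChange required fold change (default 2).
#' @return named list of gene-id vectors, one per cell type.
#' @export
deriveCellSpecificGenes <- function(reference, foldChange = 2) {
  reference <- as.matrix(reference)
  stopIfNot(ncol(reference) >= 2, "need at least 2 cell types")
  types <- colnames(reference)
  out <- stats::setNames(vector("list", length(types)), types)
  skipped <- 0L
  for (i in seq_len(nrow(reference))) {
    v <- reference[i, ]
    t <- which.max(v)
    others <- max(v[-t])
    if (others <= 0) { skipped <- skipped + 1L; next }
    if (v[t] / others > foldChange)
      out[[t]] <- c(out[[t]], rownames(reference)[i])
  }
  if (skipped > 0)
    warning(skipped, " gene(s) skipped (zero reference means in denominator)")
  lapply(out, function(g) if (is.null(g)) character() else g)
}

#' Build contamination surrogate variables
#'
#' The surrogate for a cell type in a sample is the mean of that type's
#' cell-specific genes' expression values in the sample, computed on the
#' variance-stabilized (pre-standardization) scale so between-sample level
#' differences are preserved.
#'
#' @param x \linkS4class{ExpressionData} (state `"arcsinh"` recommended; a
#'   warning is issued for standardized input).
#' @param geneLists named list of gene-id vectors per cell type.
#' @return A \linkS4class{ContaminationSurrogates}; types with no measured
#'   genes are dropped with a warning, missing listed genes are recorded in
#'   the `missingGenes` attribute.
#' @export
buildSurrogates <- function(x, geneLists) {
  if (transformState(x) == "standardized")
    warning("surrogates computed on standardized data lose level information")
  v <- exprValues(x)
  missing <- list()
  vals <- list()
  used <- list()
  for (ct in names(geneLists)) {
    genes <- unique(geneLists[[ct]])
    present <- intersect(genes, rownames(v))
    missing[[ct]] <- setdiff(genes, present)
    if (length(present) == 0) {
      warning("cell type '", ct, "' has no measured genes; surrogate dropped")
      next
    }
    vals[[ct]] <- colMeans(v[present, , drop = FALSE])
    used[[ct]] <- present
  }
  stopIfNot(length(vals) > 0, "no surrogate could be built")
  values <- do.call(cbind, vals)
  rownames(values) <- colnames(v)
  out <- new("ContaminationSurrogates", values = values,
             cellTypes = names(vals), geneLists = used)
  attr(out, "missingGenes") <- missing
  out
}

#' Re-test a SNP-pattern association with contamination covariates
#'
#' The adjusted p-value is the F-test for the genotype classes in a linear
#' model that also contains every surrogate column; the association is
#' labelled contamination-driven when it is significant before adjustment
#' but not after.
#'
#' @param pattern numeric activations over samples.
#' @param geno doses in \{0, 1, 2\} (NA allowed).
#' @param s a \linkS4class{ContaminationSurrogates} on the same samples, or
#'   `NULL` / zero columns for no adjustment.
#' @param pThreshold significance threshold (default 1e-7, the step-1
#'   suggestive threshold).
#' @return list: `pUnadjusted`, `pAdjusted`, `contaminationDriven`, `n`.
#' @export
adjustAssociation <- function(pattern, geno, s, pThreshold = 1e-7) {
  S <- if (is.null(s)) matrix(0, length(pattern), 0) else s@values
  if (ncol(S) > 0) {
    keepCols <- apply(S, 2, stats::sd) > 0
    if (!all(keepCols)) {
      warning("zero-variance surrogate column(s) dropped")
      S <- S[, keepCols, drop = FALSE]
    }
  }
  use <- !is.na(pattern) & !is.na(geno) & stats::complete.cases(S)
  y <- pattern[use]; gv <- geno[use]; Sm <- S[use, , drop = FALSE]
  rec <- anova2df(y, gv)
  if (ncol(Sm) == 0) {
    pAdj <- rec$p
  } else {
    if (qr(cbind(1, Sm))$rank < ncol(Sm) + 1)
      warning("rank-deficient surrogate design; least-norm fit used")
    cls <- sort(unique(gv))
    if (length(cls) < 2) {
      pAdj <- 1
    } else {
      Z <- outer(gv, cls[-1], `==`) + 0
      fit0 <- stats::lm.fit(cbind(1, Sm), y)
      fit1 <- stats::lm.fit(cbind(1, Sm, Z), y)
      rss0 <- sum(fit0$residuals^2)
      rss1 <- sum(fit1$residuals^2)
      dfExtra <- fit1$rank - fit0$rank
      dfRes <- length(y) - fit1$rank
      if (dfExtra < 1 || dfRes < 1 || rss1 <= 0) {
        pAdj <- if (rss1 < rss0) 0 else 1
      } else {
        Fv <- ((rss0 - rss1) / dfExtra) / (rss1 / dfRes)
        pAdj <- stats::pf(Fv, dfExtra, dfRes, lower.tail = FALSE)
      }
    }
  }
  list(pUnadjusted = rec$p, pAdjusted = pAdj,
       contaminationDriven = rec$p < pThreshold && pAdj >= pThreshold,
       n = sum(use))
}
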