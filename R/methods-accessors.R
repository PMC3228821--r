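#' @rdname ExpressionData-class
#' @export
setMethod("exprValues", "ExpressionData",
          function(x) assay(x, "exprs"))

#' @rdname ExpressionData-class
#' @export
setMethod("detectionP", "ExpressionData", function(x) {
  if ("detection" %in% assayNames(x)) assay(x, "detection") else NULL
})

#' @rdname ExpressionData-class
#' @export
setMethod("transformState", "ExpressionData",
          function(x) x@transformState)

setMethod("show", "ExpressionData", function(object) {
  cat(sprintf("ExpressionData: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@transformState))
  if ("detection" %in% assayNames(object))
    cat("  with detection p-values\n")
})

#' @rdname GenotypeData-class
#' @export
setMethod("doseMatrix", "GenotypeData", function(x) assay(x, "dose"))

#' @rdname GenotypeData-class
#' @export
setMethod("variantMap", "GenotypeData", function(x) {
  data.frame(snp = rownames(x),
             chrom = rowData(x)$chrom,
             pos = rowData(x)$pos,
             row.names = NULL)
})

#' @rdname GenotypeData-class
#' @export
setMethod("minorAlleleFreq", "GenotypeData", function(x) {
  d <- assay(x, "dose")
  f <- rowMeans(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
})

#' @rdname GenotypeData-class
#' @export
setMethod("callRate", "GenotypeData", function(x) {
  d <- assay(x, "dose")
  rowMeans(!is.na(d))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
})

#' @rdname Decomposition-class
#' @export
setMethod("signatures", "Decomposition", function(x) x@S)

#' @rdname Decomposition-class
#' @export
setMethod("patterns", "Decomposition", function(x) x@A)

#' @rdname Decomposition-class
#' @export
setMethod("componentIds", "Decomposition", function(x) x@componentIds)

#' @rdname Decomposition-class
#' @export
setMethod("componentKurtosis", "Decomposition", function(x) {
  stats::setNames(x@kurtosis, x@componentIds)
})

#' @rdname Decomposition-class
#' @export
setMethod("numComponents", "Decomposition", function(x) ncol(x@S))

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition: %d genes, %d samples, K = %d\n",
              nrow(object@S), ncol(object@A), ncol(object@S)))
  if (length(object@kurtosis))
    cat(sprintf("  excess kurtosis: %s\n",
                paste(sprintf("%.2f", utils::head(object@kurtosis, 8)),
                      collapse = ", ")))
  if (length(object@individualSpecific))
    cat(sprintf("  individual-specific: %d; kurtosis pass: %d\n",
                sum(object@individualSpecific),
                sum(object@kurtosisPass)))
})

#' @rdname GeneModule-class
#' @export
setMethod("moduleGenes", "GeneModule",
          function(x) as.character(x@members$gene))

#' @rdname GeneModule-class
#' @export
setMethod("moduleSize", "GeneModule", function(x) nrow(x@members))

#' @rdname GeneModule-class
#' @export
setMethod("moduleTable", "GeneModule", function(x) {
  df <- as.data.frame(x@members)
  df$component <- x@componentId
  df[, c("component", "gene", "loading", "q")]
})

setMethod("show", "GeneModule", function(object) {
  cat(sprintf("GeneModule '%s': %d genes (FDR < %g)\n",
              object@componentId, nrow(object@members), object@fdrMax))
})

setMethod("show", "NullFit", function(object) {
  cat(sprintf("NullFit: center %.4g, sigma0 %.4g, eta0 %.3f\n",
              object@center, object@sigma0, object@eta0))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d genes x %d samples, %d SNPs, K_true = %d\n",
    object@nGenes, object@nSamples, object@nSnps, object@kTrue))
  cat(sprintf("  module sizes: %s; seed %d\n",
              paste(object@moduleSizes, collapse = ", "), object@seed))
  if (length(object@contamination))
    cat(sprintf("  contamination: %d cell types\n",
                object@contamination$nCellTypes))
})
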