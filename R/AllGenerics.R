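#' @rdname ExpressionData-class
#' @param x an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionData-class
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname ExpressionData-class
#' @export
setGeneric("transformState", function(x) standardGeneric("transformState"))

#' @rdname GenotypeData-class
#' @param x an object.
#' @export
setGeneric("doseMatrix", function(x) standardGeneric("doseMatrix"))

#' @rdname GenotypeData-class
#' @export
setGeneric("variantMap", function(x) standardGeneric("variantMap"))

#' @rdname GenotypeData-class
#' @export
setGeneric("minorAlleleFreq", function(x) standardGeneric("minorAlleleFreq"))

#' @rdname GenotypeData-class
#' @export
setGeneric("callRate", function(x) standardGeneric("callRate"))

#' @rdname Decomposition-class
#' @param x an object.
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname Decomposition-class
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname Decomposition-class
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))

#' @rdname Decomposition-class
#' @export
setGeneric("componentKurtosis",
           function(x) standardGeneric("componentKurtosis"))

#' @rdname Decomposition-class
#' @export
setGeneric("numComponents", function(x) standardGeneric("numComponents"))

#' @rdname GeneModule-class
#' @param x an object.
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname GeneModule-class
#' @export
setGeneric("moduleSize", function(x) standardGeneric("moduleSize"))

#' @rdname GeneModule-class
#' @export
setGeneric("moduleTable", function(x) standardGeneric("moduleTable"))
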